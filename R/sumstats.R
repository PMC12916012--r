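#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistics file into a `sumstats` object: a
#' data.frame with one row per variant and standardized columns `id`,
#' `chrom`, `pos`, `ea` (effect allele), `oa` (other allele), `z`, `n`, and
#' optionally `maf`. If the file carries `beta` and `se` instead of a
#' Z-score, `z = beta / se` is computed. Rows with missing or non-finite
#' values in required fields (including `se == 0`) are dropped and counted
#' in the attached report.
#'
#' @param path Delimited text file with a header (tab/comma/whitespace are
#'   auto-detected by [data.table::fread()]).
#' @param column_map Named character vector/list mapping standardized names
#'   to file column names. Recognized keys: `id`, `chrom`, `pos`, `ea`,
#'   `oa`, `z` (or `beta` and `se`), `n`, `maf`. `id` plus either `z` or
#'   `beta`+`se` are required; the rest are optional.
#' @param trait_label Label stored with the object.
#' @param n Scalar sample size used if the file has no N column.
#'
#' @return A data.frame of class `sumstats` with attributes `trait_label`
#'   and `drop_report` (named counts of rows removed and why).
#' @export
read_sumstats <- function(path, column_map, trait_label = "trait", n = NULL) {
  column_map <- as.list(column_map)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- function(key) {
    cn <- column_map[[key]]
    if (is.null(cn)) return(NULL)
    if (!cn %in% names(dt))
      stop(sprintf("mapped column '%s' (for %s) not found in %s", cn, key, path))
    dt[[cn]]
  }
  out <- data.frame(id = as.character(need("id")), stringsAsFactors = FALSE)
  if (!nrow(out) || is.null(column_map$id)) stop("column_map must name an 'id' column")

  for (key in c("chrom", "pos", "ea", "oa", "maf")) {
    v <- need(key)
    if (!is.null(v)) out[[key]] <- v
  }
  n_zero_se <- 0L
  if (!is.null(column_map$z)) {
    out$z <- as.numeric(need("z"))
  } else if (!is.null(column_map$beta) && !is.null(column_map$se)) {
    beta <- as.numeric(need("beta"))
    se <- as.numeric(need("se"))
    bad_se <- is.finite(se) & se == 0
    n_zero_se <- sum(bad_se)
    se[bad_se] <- NA_real_
    out$z <- beta / se
  } else {
    stop("column_map must provide 'z' or both 'beta' and 'se'")
  }
  nv <- need("n")
  out$n <- if (!is.null(nv)) as.numeric(nv) else
    if (!is.null(n)) rep(as.numeric(n), nrow(out)) else
      stop("no sample-size column mapped and no scalar n supplied")

  if ("pos" %in% names(out)) out$pos <- as.numeric(out$pos)
  bad_z <- !is.finite(out$z)
  ok <- !bad_z & is.finite(out$n) & out$n > 0 & !is.na(out$id)
  dropped <- c(dropped = sum(!ok),
               missing_z = sum(bad_z) - n_zero_se,
               zero_se = n_zero_se,
               other = sum(!ok & !bad_z))
  out <- out[ok, , drop = FALSE]
  if (!nrow(out)) stop("no usable rows after filtering: ", path)
  if (anyDuplicated(out$id)) stop("duplicated variant IDs in ", path)
  for (al in intersect(c("ea", "oa"), names(out)))
    out[[al]] <- toupper(as.character(out[[al]]))
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            trait_label = trait_label, drop_report = dropped)
}

#' Construct a sumstats object from vectors
#'
#' In-memory constructor used by the simulator and by tests; performs the
#' same validation as [read_sumstats()].
#'
#' @param id Variant identifiers (unique).
#' @param z Z-scores (finite).
#' @param n Sample size, scalar or per variant (> 0).
#' @param chrom,pos,ea,oa,maf Optional per-variant annotation.
#' @param trait_label Label stored with the object.
#' @return A `sumstats` data.frame.
#' @export
sumstats <- function(id, z, n, chrom = NULL, pos = NULL, ea = NULL, oa = NULL,
                     maf = NULL, trait_label = "trait") {
  out <- data.frame(id = as.character(id), stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("variant IDs must be unique")
  if (!is.null(chrom)) out$chrom <- chrom
  if (!is.null(pos)) out$pos <- as.numeric(pos)
  if (!is.null(ea)) out$ea <- toupper(as.character(ea))
  if (!is.null(oa)) out$oa <- toupper(as.character(oa))
  if (!is.null(maf)) out$maf <- as.numeric(maf)
  out$z <- as.numeric(z)
  out$n <- rep_len(as.numeric(n), nrow(out))
  if (any(!is.finite(out$z))) stop("z must be finite")
  if (any(out$n <= 0)) stop("n must be positive")
  structure(out, class = c("sumstats", "data.frame"),
            trait_label = trait_label,
            drop_report = c(missing_z = 0L, zero_se = 0L, nonfinite = 0L))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats '%s': %d variants, median N = %g\n",
              attr(x, "trait_label"), nrow(x), stats::median(x$n)))
  NextMethod()
}

.palindromic <- function(ea, oa) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  p <- comp[ea] == oa
  p[is.na(p)] <- FALSE
  unname(p)
}

#' Harmonize summary statistics against a reference variant table
#'
#' Aligns a trait's summary statistics to the allele orientation and variant
#' order of an LD reference so that two traits' Z-scores can share one LD
#' panel. Variants are reordered to match `ref`; where the effect/other
#' alleles are swapped relative to the reference the Z-score sign is
#' flipped; strand-ambiguous palindromic variants (A/T, C/G) are dropped, as
#' are variants absent from the reference or with alleles irreconcilable
#' with it. Harmonizing an already-harmonized object is a no-op.
#'
#' @param ss A [sumstats()] object with `ea`/`oa` columns.
#' @param ref Data.frame with columns `id`, `ea`, and optionally `oa`, in LD
#'   block order (e.g. built from an [ld_block()]'s `variant_ids`).
#' @return A `sumstats` in `ref` order with attribute `harmonize_report`
#'   (counts: kept, flipped, dropped_palindromic, dropped_unmatched,
#'   dropped_mismatch).
#' @export
harmonize <- function(ss, ref) {
  if (!all(c("ea", "oa") %in% names(ss)))
    stop("sumstats must carry 'ea' and 'oa' alleles to harmonize")
  if (!all(c("id", "ea") %in% names(ref)))
    stop("ref must carry 'id' and 'ea'")
  ref_id <- as.character(ref$id)
  ref_ea <- toupper(as.character(ref$ea))
  ref_oa <- if ("oa" %in% names(ref)) toupper(as.character(ref$oa)) else NULL

  m <- match(ref_id, ss$id)
  present <- !is.na(m)
  dropped_unmatched <- nrow(ss) - sum(present)
  out <- ss[m[present], , drop = FALSE]
  r_ea <- ref_ea[present]
  r_oa <- if (!is.null(ref_oa)) ref_oa[present] else NULL

  pal <- .palindromic(out$ea, out$oa)
  if (is.null(r_oa)) {
    same <- out$ea == r_ea
    flip <- out$oa == r_ea
  } else {
    same <- out$ea == r_ea & out$oa == r_oa
    flip <- out$oa == r_ea & out$ea == r_oa
  }
  keep <- !pal & (same | flip)
  flipped <- flip & keep

  out$z[flipped] <- -out$z[flipped]
  if (all(c("ea", "oa") %in% names(out))) {
    tmp <- out$ea[flipped]
    out$ea[flipped] <- out$oa[flipped]
    out$oa[flipped] <- tmp
  }
  report <- c(kept = sum(keep), flipped = sum(flipped),
              dropped_palindromic = sum(pal),
              dropped_unmatched = dropped_unmatched,
              dropped_mismatch = sum(!keep & !pal))
  out <- out[keep, , drop = FALSE]
  if (nrow(out) < 2L) stop("fewer than 2 variants survive harmonization")
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            trait_label = attr(ss, "trait_label"),
            drop_report = attr(ss, "drop_report"),
            harmonize_report = report)
}

#' Restrict summary statistics to a gene's cis window
#'
#' Keeps variants within `gene_start - window` to `gene_end + window`
#' (closed interval, 1-based coordinates) on the gene's chromosome. The
#' default window of 1 Mb on each side is the conventional cis-region
#' definition for molecular QTL analysis.
#'
#' @param ss A [sumstats()] with `chrom` and `pos`.
#' @param gene_chrom,gene_start,gene_end Gene location (1-based, closed).
#' @param window Flank size in bp on each side (default 1e6).
#' @return The windowed `sumstats`.
#' @export
extract_cis_region <- function(ss, gene_chrom, gene_start, gene_end,
                               window = 1e6) {
  if (!all(c("chrom", "pos") %in% names(ss)))
    stop("sumstats must carry 'chrom' and 'pos'")
  keep <- as.character(ss$chrom) == as.character(gene_chrom) &
    ss$pos >= gene_start - window & ss$pos <= gene_end + window
  if (!any(keep)) stop("no variants in the cis window")
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("class", "trait_label", "drop_report")] <-
    attributes(ss)[c("class", "trait_label", "drop_report")]
  out
}

#' Exclude rare variants by minor allele frequency
#'
#' Removes variants with `maf < threshold` (strict inequality: a variant at
#' exactly the threshold is retained).
#'
#' @param ss A [sumstats()] with a `maf` column.
#' @param threshold MAF exclusion threshold (default 0.05).
#' @return The filtered `sumstats` (possibly empty, with a warning).
#' @export
filter_maf <- function(ss, threshold = 0.05) {
  if (!"maf" %in% names(ss)) stop("sumstats has no 'maf' column")
  if (any(ss$maf < 0 | ss$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  keep <- !is.na(ss$maf) & ss$maf >= threshold
  if (!any(keep)) warning("no variants remain after MAF filtering")
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("class", "trait_label", "drop_report")] <-
    attributes(ss)[c("class", "trait_label", "drop_report")]
  out
}

#' Heritability explained by the top associated variant
#'
#' For the variant with the largest `|Z|`, returns `z^2 / (N + z^2)` using
#' that variant's sample size: the proportion of trait variance explained
#' by the single most strongly associated variant in the region. Values lie
#' in `[0, 1)` and are invariant to the signs of the Z-scores.
#'
#' @param ss A [sumstats()] object.
#' @return Scalar top-variant heritability.
#' @export
top_snp_h2 <- function(ss) {
  if (!nrow(ss)) stop("empty sumstats")
  if (any(ss$n <= 0)) stop("non-positive sample size")
  j <- which.max(abs(ss$z))
  z2 <- ss$z[j]^2
  z2 / (ss$n[j] + z2)
}

#' Read region definitions
#'
#' Accepts either a gene table (columns `gene`, `chrom`, `start`, `end`;
#' 1-based closed) or BED (`chrom`, `start`, `end`, optional `name`;
#' 0-based half-open, converted to 1-based closed on read).
#'
#' @param path Delimited text file.
#' @param format `"genes"` (header expected) or `"bed"` (headerless).
#' @return Data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_regions <- function(path, format = c("genes", "bed")) {
  format <- match.arg(format)
  if (format == "genes") {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(dt)))
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    dt[need]
  } else {
    dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
    if (ncol(dt) < 3) stop("BED needs at least 3 columns")
    data.frame(gene = if (ncol(dt) >= 4) as.character(dt[[4]]) else
                 paste0("region", seq_len(nrow(dt))),
               chrom = as.character(dt[[1]]),
               start = as.numeric(dt[[2]]) + 1,  # 0-based half-open -> 1-based closed
               end = as.numeric(dt[[3]]),
               stringsAsFactors = FALSE)
  }
}
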