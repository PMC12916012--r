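#' Construct an LD block from a correlation matrix
#'
#' An `ld_block` holds everything the regional likelihood needs about a
#' region's linkage disequilibrium (LD): the correlation matrix `R`, the LD
#' score matrix `L = R %*% R` (its diagonal entries are the classical
#' per-variant LD scores), and the eigen-decomposition of `R` shared by both.
#' Because `L` is the matrix square of `R`, the two matrices are
#' simultaneously diagonalizable: every covariance matrix the model builds
#' from them has the same eigenvectors, which is what makes the likelihood a
#' sum of small per-eigenvalue terms rather than a dense multivariate-normal
#' evaluation.
#'
#' Numerically null eigen-directions (reference-panel noise, duplicated
#' variants) are discarded: eigenvalues at or below `trunc_tol` are dropped
#' together with their eigenvectors, and the likelihood is evaluated on the
#' retained sub-space only.
#'
#' @param R Square symmetric correlation matrix (unit diagonal). Small
#'   asymmetries (below 1e-10 after averaging) and diagonal drift are
#'   repaired; entries must lie in `[-1, 1]` up to 1e-8 slack.
#' @param variant_ids Character vector of variant identifiers, one per
#'   row/column of `R`. Defaults to the dimnames of `R` or `snp1..snpM`.
#' @param trunc_tol Eigenvalue truncation threshold; eigenvalues `<=`
#'   this value are dropped. Default `1e-8 * max(eigenvalue)`.
#'
#' @return An object of class `ld_block`: a list with elements
#'   `variant_ids`, `M`, `R`, `L`, `eigvals` (descending, all `> trunc_tol`),
#'   `eigvecs` (orthonormal columns), `K` (number retained), `trunc_tol`.
#'
#' @examples
#' blk <- ld_block(diag(3))
#' blk$K          # 3
#' diag(blk$L)    # all 1: a variant's LD score includes itself
#'
#' @seealso [simulate_ld_ar1()], [simulate_ld_blocks()], [read_ld_matrix()]
#' @export
ld_block <- function(R, variant_ids = NULL, trunc_tol = NULL) {
  R <- as.matrix(R)
  if (!is.numeric(R) || nrow(R) != ncol(R))
    stop("R must be a square numeric matrix")
  M <- nrow(R)
  if (M < 2L) stop("an LD block needs at least 2 variants")
  if (any(!is.finite(R))) stop("R contains non-finite entries")
  if (any(R < -1 - 1e-8) || any(R > 1 + 1e-8))
    stop("R has entries outside [-1, 1]")
  if (is.null(variant_ids)) {
    variant_ids <- rownames(R)
    if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_len(M))
  }
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != M)
    stop("length(variant_ids) does not match dim(R)")
  if (anyDuplicated(variant_ids))
    stop("variant_ids must be unique")

  if (max(abs(R - t(R))) > 1e-6)
    warning("R is noticeably asymmetric; symmetrizing")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(variant_ids, variant_ids)

  ed <- eigen(R, symmetric = TRUE)
  if (is.null(trunc_tol)) trunc_tol <- 1e-8 * max(ed$values)
  if (trunc_tol < 0) stop("trunc_tol must be >= 0")
  keep <- ed$values > trunc_tol
  if (!any(keep))
    stop("degenerate region: all eigenvalues at or below trunc_tol")

  structure(
    list(variant_ids = variant_ids,
         M = M,
         R = R,
         L = R %*% R,
         eigvals = ed$values[keep],
         eigvecs = ed$vectors[, keep, drop = FALSE],
         K = sum(keep),
         trunc_tol = trunc_tol),
    class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  cat(sprintf("LD block: %d variants, %d eigen-directions retained (trunc_tol = %.3g)\n",
              x$M, x$K, x$trunc_tol))
  cat(sprintf("  eigenvalues: max %.4g, min retained %.4g\n",
              max(x$eigvals), min(x$eigvals)))
  invisible(x)
}

#' Autoregressive AR(1) LD matrix
#'
#' Builds the deterministic LD block with `R[i, j] = rho^|i - j|`, the
#' standard stand-in for the decaying correlation structure of a cis region.
#' AR(1) correlation matrices are positive definite for any `|rho| < 1`.
#'
#' @param M Number of variants (>= 2).
#' @param rho Adjacent-variant correlation, in (-1, 1).
#' @param variant_prefix Prefix for generated variant IDs.
#' @inheritParams ld_block
#' @return An [ld_block()].
#' @export
simulate_ld_ar1 <- function(M, rho, variant_prefix = "snp", trunc_tol = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  idx <- seq_len(M)
  R <- rho^abs(outer(idx, idx, "-"))
  ld_block(R, variant_ids = paste0(variant_prefix, idx), trunc_tol = trunc_tol)
}

#' Block-diagonal compound-symmetry LD matrix
#'
#' Contiguous blocks with constant within-block correlation `within_rho` and
#' zero correlation across blocks; the last block absorbs any remainder of
#' `M`. Each block of size `b` has eigenvalues `1 + (b - 1) * within_rho`
#' (once) and `1 - within_rho` (`b - 1` times).
#'
#' @param M Number of variants.
#' @param n_blocks Number of contiguous blocks (1..M).
#' @param within_rho Within-block correlation, in `[0, 1)`.
#' @param seed Optional integer; reserved for jittered variants of this
#'   generator, the plain compound-symmetry matrix is deterministic.
#' @inheritParams ld_block
#' @return An [ld_block()].
#' @export
simulate_ld_blocks <- function(M, n_blocks, within_rho, seed = NULL,
                               trunc_tol = NULL) {
  if (within_rho < 0 || within_rho >= 1)
    stop("within_rho must be in [0, 1)")
  if (n_blocks < 1 || n_blocks > M) stop("n_blocks must be in 1..M")
  base <- M %/% n_blocks
  sizes <- rep(base, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + M - sum(sizes)
  R <- matrix(0, M, M)
  at <- 0L
  for (b in sizes) {
    idx <- at + seq_len(b)
    R[idx, idx] <- within_rho
    at <- at + b
  }
  diag(R) <- 1
  ld_block(R, variant_ids = paste0("snp", seq_len(M)), trunc_tol = trunc_tol)
}

#' Read an LD matrix from disk
#'
#' Two on-disk layouts are supported and produce identical blocks:
#' a dense square text matrix (whitespace- or comma-delimited, no header),
#' or a binary file of doubles (row-major or column-major is immaterial for
#' a symmetric matrix) accompanied by a sidecar variant-list file. The
#' variant list, one ID per line in matrix order, may be supplied for the
#' text layout too.
#'
#' @param path Path to the matrix file.
#' @param snplist_path Optional path to the sidecar variant list. Required
#'   for binary input (it determines the dimension).
#' @param binary If `TRUE`, read `path` as a flat vector of doubles.
#' @inheritParams ld_block
#' @return An [ld_block()].
#' @export
read_ld_matrix <- function(path, snplist_path = NULL, binary = FALSE,
                           trunc_tol = NULL) {
  ids <- NULL
  if (!is.null(snplist_path)) {
    ids <- readLines(snplist_path)
    ids <- ids[nzchar(ids)]
  }
  if (binary) {
    if (is.null(ids))
      stop("binary LD input requires a sidecar variant list")
    M <- length(ids)
    vals <- readBin(path, what = "double", n = M * M + 1L)
    if (length(vals) != M * M)
      stop("binary LD file size does not match the variant list")
    R <- matrix(vals, M, M)
  } else {
    R <- as.matrix(data.table::fread(path, header = FALSE))
    if (!is.null(ids) && length(ids) != nrow(R))
      stop("variant list length does not match the LD matrix dimension")
  }
  ld_block(R, variant_ids = ids, trunc_tol = trunc_tol)
}
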