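#' Draw correlated causal effect sizes for two traits
#'
#' Per causal variant, the pair of effects is bivariate normal with
#' variances `h1_sq / m` and `h2_sq / m` and correlation `rG`, so the total
#' genetic variance of each trait sums (in expectation) to its regional
#' heritability. The degenerate cases `rG = +/-1` are exact: the second
#' trait's effects are a deterministic rescaling of the first's.
#'
#' @param m Number of causal variants (>= 1).
#' @param h1_sq,h2_sq Regional heritabilities of the two traits.
#' @param rG True genetic correlation in `[-1, 1]`.
#' @param seed Optional integer seed.
#' @return List with numeric vectors `beta1`, `beta2` of length `m`.
#' @export
draw_effects <- function(m, h1_sq, h2_sq, rG, seed = NULL) {
  if (m < 1) stop("m must be >= 1")
  if (abs(rG) > 1) stop("|rG| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::rnorm(m)
  v <- stats::rnorm(m)
  beta1 <- sqrt(h1_sq / m) * u
  beta2 <- sqrt(h2_sq / m) * (rG * u + sqrt(max(0, 1 - rG^2)) * v)
  list(beta1 = beta1, beta2 = beta2)
}

#' Simulate standardized genotypes with a given LD structure
#'
#' Rows are drawn from `N(0, R)` using the block's eigen-decomposition and
#' columns are then standardized to mean 0, variance 1. An optional
#' Gaussian-copula discretization to 0/1/2 dosages at a given minor allele
#' frequency is available for realism checks; the continuous default is
#' what the summary-statistics likelihood sees in either case.
#'
#' @param N Number of individuals (>= 2).
#' @param block An [ld_block()].
#' @param seed Optional integer seed.
#' @param discretize If `TRUE`, threshold the latent Gaussians into 0/1/2
#'   dosages at `maf` before standardizing.
#' @param maf Minor allele frequency for the discretized mode.
#' @return `N x M` matrix of column-standardized genotypes.
#' @export
simulate_genotypes <- function(N, block, seed = NULL, discretize = FALSE,
                               maf = 0.3) {
  if (N < 2) stop("N must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(stats::rnorm(N * block$K), N, block$K)
  X <- E %*% (t(block$eigvecs) * sqrt(block$eigvals))
  if (discretize) {
    q <- stats::qnorm(c((1 - maf)^2, 1 - maf^2))
    X <- matrix(findInterval(X, q), N, block$M)
  }
  scale(X)[, , drop = FALSE]
}

#' Simulate a phenotype from genotypes and causal effects
#'
#' `y = X[, causal_idx] %*% beta + e` with independent residuals
#' `e ~ N(0, 1 - h_sq)`, so that the total phenotypic variance is 1 in
#' expectation when the genetic component explains `h_sq`.
#'
#' @param X Standardized genotype matrix.
#' @param causal_idx Column indices of the causal variants.
#' @param beta Effect sizes, one per causal variant.
#' @param h_sq Regional heritability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector of length `nrow(X)`.
#' @export
simulate_phenotypes <- function(X, causal_idx, beta, h_sq, seed = NULL) {
  if (length(causal_idx) != length(beta))
    stop("causal_idx and beta lengths differ")
  if (h_sq < 0 || h_sq >= 1) stop("h_sq must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  g <- if (length(beta)) drop(X[, causal_idx, drop = FALSE] %*% beta) else 0
  g + stats::rnorm(nrow(X), sd = sqrt(1 - h_sq))
}

#' Per-variant GWAS Z-scores by marginal regression
#'
#' Regresses the phenotype on each standardized genotype column separately;
#' the Z-score equals `sqrt(N - 2) * r / sqrt(1 - r^2)` where `r` is the
#' sample correlation, which is the t-statistic of the simple-regression
#' slope. Correlations are clipped at `1 - 1e-12` in magnitude so a column
#' identical to the phenotype yields a large finite Z.
#'
#' @param X Standardized genotype matrix.
#' @param y Phenotype vector.
#' @return Numeric vector of Z-scores, one per column of `X`.
#' @export
gwas_zscores <- function(X, y) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance genotype column")
  r <- drop(stats::cor(X, y))
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  sqrt(nrow(X) - 2) * r / sqrt(1 - r^2)
}

#' Sample Z-scores directly from the summary-statistics model
#'
#' Draws `(z1, z2)` from the bivariate Gaussian model that the likelihood
#' assumes (the infinitesimal polygenic model): independently for each
#' retained eigenvalue, the projected pair is sampled from its 2x2
#' covariance and the result is rotated back to variant space. Orders of
#' magnitude faster than simulating individuals, and exact under the model.
#'
#' @inheritParams loglik_joint
#' @param seed Optional integer seed.
#' @return List with Z-score vectors `z1`, `z2` (length `block$M`).
#' @export
simulate_sumstats_direct <- function(block, h1_sq, h2_sq, h12, N1, N2,
                                     seed = NULL) {
  if (h1_sq < 0 || h2_sq < 0) stop("heritabilities must be >= 0")
  if (abs(h12) > sqrt(h1_sq * h2_sq) + 1e-12)
    stop("|h12| exceeds sqrt(h1_sq * h2_sq)")
  if (!is.null(seed)) set.seed(seed)
  lam <- block$eigvals
  s1 <- N1 * h1_sq * lam^2 / block$M + lam
  s2 <- N2 * h2_sq * lam^2 / block$M + lam
  cc <- sqrt(N1 * N2) * h12 * lam^2 / block$M
  e1 <- stats::rnorm(block$K)
  e2 <- stats::rnorm(block$K)
  w1 <- sqrt(s1) * e1
  cond_var <- pmax(s2 - cc^2 / s1, 0)
  w2 <- (cc / sqrt(s1)) * e1 + sqrt(cond_var) * e2
  list(z1 = drop(block$eigvecs %*% w1),
       z2 = drop(block$eigvecs %*% w2))
}

#' Sample Z-scores conditional on drawn causal effects
#'
#' Summary-level counterpart of the individual-level pipeline for a finite
#' causal architecture: given standardized effects `beta` at the causal
#' variants, the marginal Z-scores are centred at `sqrt(N) * R[, causal]
#' %*% beta` with residual covariance `R`, the large-N behaviour of
#' per-variant regression on standardized genotypes. Noise is shared
#' eigen-space Gaussian, independent between traits (no sample overlap).
#'
#' @param block An [ld_block()].
#' @param causal_idx Indices of causal variants.
#' @param beta1,beta2 Effect vectors at the causal variants.
#' @param N1,N2 Sample sizes.
#' @param seed Optional integer seed.
#' @return List with Z-score vectors `z1`, `z2`.
#' @export
simulate_sumstats_fixed <- function(block, causal_idx, beta1, beta2,
                                    N1, N2, seed = NULL) {
  simulate_sumstats_fixed2(block, causal_idx, causal_idx, beta1, beta2,
                           N1, N2, seed = seed)
}

#' @rdname simulate_sumstats_fixed
#' @param causal_idx1,causal_idx2 Per-trait causal variant indices, for
#'   scenarios where the two traits' causal architectures do not coincide.
#' @export
simulate_sumstats_fixed2 <- function(block, causal_idx1, causal_idx2,
                                     beta1, beta2, N1, N2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu1 <- sqrt(N1) * drop(block$R[, causal_idx1, drop = FALSE] %*% beta1)
  mu2 <- sqrt(N2) * drop(block$R[, causal_idx2, drop = FALSE] %*% beta2)
  noise <- function() {
    drop(block$eigvecs %*% (sqrt(block$eigvals) * stats::rnorm(block$K)))
  }
  list(z1 = mu1 + noise(), z2 = mu2 + noise())
}

#' Synthetic stand-in distribution of cis top-variant heritabilities
#'
#' Samples protein-trait regional heritabilities from a right-skewed
#' log-normal (meanlog = log(0.04), sdlog = 1, truncated to
#' `[0.001, 0.5]`). This is a synthetic stand-in for the empirical
#' distribution of top-variant heritabilities across cis regions of a
#' large plasma-proteome panel, used when no user-supplied list of
#' heritabilities is given.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of heritabilities in `[0.001, 0.5]`.
#' @export
top_h2_standin <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rlnorm(n, meanlog = log(0.04), sdlog = 1)
  pmin(pmax(x, 0.001), 0.5)
}

#' Define a simulation scenario
#'
#' A scenario fixes everything one sweep needs: the LD block, the causal
#' architecture (a causal fraction or an explicit causal count), the
#' heritability and genetic-correlation grids, the GWAS sample sizes, the
#' number of replicates per grid cell, the simulation mode, and the master
#' seed. The default grids are the polygenic evaluation design: 10% of
#' variants causal, disease-trait heritability in {0.001, 0.01, 0.1},
#' genetic correlation in {0, 0.3, 0.5, 0.8, 1}, 100 replicates per cell.
#'
#' `h1_source` controls the protein-trait heritability: a fixed numeric
#' vector to resample from, or `"standin"` for the built-in synthetic
#' top-variant distribution ([top_h2_standin()]).
#'
#' @param block An [ld_block()] shared by all replicates.
#' @param causal_fraction Fraction of variants that are causal (used when
#'   `causal_count` is `NULL`).
#' @param causal_count Explicit number of causal variants (e.g. 1, 3, 5);
#'   overrides `causal_fraction`.
#' @param h1_source `"standin"` or a numeric vector of protein-trait
#'   heritabilities to resample from.
#' @param h2_grid Disease-trait heritability grid.
#' @param rg_grid True genetic-correlation grid.
#' @param N1,N2 Sample sizes for traits 1 (protein) and 2 (disease).
#' @param n_replicates Replicates per grid cell (default 100).
#' @param mode `"direct"` (summary-level sampling conditional on drawn
#'   effects) or `"individual"` (simulate genotypes and phenotypes, then
#'   run per-variant regressions).
#' @param seed Master seed; per-replicate seeds derive from it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(block,
                         causal_fraction = 0.10,
                         causal_count = NULL,
                         h1_source = "standin",
                         h2_grid = c(0.001, 0.01, 0.1),
                         rg_grid = c(0, 0.3, 0.5, 0.8, 1),
                         N1 = 30000, N2 = 300000,
                         n_replicates = 100L,
                         mode = c("direct", "individual"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(block, "ld_block")) stop("block must be an ld_block")
  if (!length(h2_grid) || !length(rg_grid)) stop("grids must be non-empty")
  if (any(h2_grid < 0 | h2_grid >= 1)) stop("h2 values must be in [0, 1)")
  if (any(abs(rg_grid) > 1)) stop("rG values must be in [-1, 1]")
  if (is.null(causal_count)) {
    if (causal_fraction <= 0 || causal_fraction > 1)
      stop("causal_fraction must be in (0, 1]")
    m <- max(1L, round(causal_fraction * block$M))
  } else {
    if (causal_count < 1) stop("causal_count must be >= 1")
    m <- as.integer(causal_count)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(block = block, m_causal = m,
                 causal_fraction = causal_fraction,
                 causal_count = causal_count,
                 h1_source = h1_source, h2_grid = h2_grid,
                 rg_grid = rg_grid, N1 = N1, N2 = N2,
                 n_replicates = as.integer(n_replicates),
                 mode = mode, seed = as.integer(seed)),
            class = "sim_scenario")
}

# deterministic per-replicate seed, kept well below 2^31
.replicate_seed <- function(master, cell, rep) {
  (master * 1009L + cell * 131071L + rep * 7L) %% 2147483647L
}

#' Run a simulation scenario through the colocalization test
#'
#' Iterates the scenario's full grid times replicates. Each replicate draws
#' a protein-trait heritability from `h1_source`, places the causal
#' variants uniformly at random, draws their effects, generates Z-scores in
#' the requested mode, and runs [hdlc_test()] at each `r0` in `r0_list`.
#' Per-replicate seeds derive deterministically from the scenario seed, so
#' reruns reproduce the table exactly. Individual replicate failures are
#' recorded as flagged rows, not raised.
#'
#' @param scenario A [sim_scenario()].
#' @param r0_list Numeric vector of thresholds to test at (default
#'   `c(0, 0.5)`).
#' @param out_tsv Optional path: rows are appended as each grid cell
#'   finishes, and cells already present in the file are skipped (resume).
#' @param compute_ci Forwarded to [hdlc_test()]; default `FALSE` for speed.
#' @return Data.frame with one row per replicate x r0: truth columns
#'   (`h1_true`, `h2_true`, `rg_true`, `m_causal`, `replicate`, `seed`),
#'   estimates, `lambda`, `pvalue`, and `flags`.
#' @export
run_scenario <- function(scenario, r0_list = c(0, 0.5), out_tsv = NULL,
                         compute_ci = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  blk <- scenario$block
  grid <- expand.grid(h2_true = scenario$h2_grid, rg_true = scenario$rg_grid,
                      KEEP.OUT.ATTRS = FALSE)
  done <- NULL
  prev <- NULL
  if (!is.null(out_tsv) && file.exists(out_tsv)) {
    prev <- data.table::fread(out_tsv, data.table = FALSE)
    if ("flags" %in% names(prev)) prev$flags <- as.character(prev$flags)
    done <- unique(prev[c("h2_true", "rg_true")])
  }
  rows <- vector("list", nrow(grid) + 1L)
  rows[[nrow(grid) + 1L]] <- prev
  for (ci in seq_len(nrow(grid))) {
    h2t <- grid$h2_true[ci]
    rgt <- grid$rg_true[ci]
    if (!is.null(done) &&
        any(abs(done$h2_true - h2t) < 1e-12 & abs(done$rg_true - rgt) < 1e-12))
      next
    cell_rows <- vector("list", scenario$n_replicates)
    for (rep_i in seq_len(scenario$n_replicates)) {
      sd_i <- .replicate_seed(scenario$seed, ci, rep_i)
      cell_rows[[rep_i]] <- .one_replicate(scenario, blk, h2t, rgt, rep_i,
                                           sd_i, r0_list, compute_ci)
    }
    cell <- do.call(rbind, cell_rows)
    rows[[ci]] <- cell
    if (!is.null(out_tsv))
      data.table::fwrite(cell, out_tsv, sep = "\t",
                         append = file.exists(out_tsv))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

.one_replicate <- function(scenario, blk, h2t, rgt, rep_i, sd_i, r0_list,
                           compute_ci) {
  set.seed(sd_i)
  h1t <- if (identical(scenario$h1_source, "standin"))
    top_h2_standin(1) else sample(scenario$h1_source, 1)
  m <- scenario$m_causal
  # rG != 0: one causal set shared by both traits, jointly drawn effects.
  # rG == 0 (the colocalization-negative scenario): each trait gets its own
  # independently placed causal set, so the region carries two unrelated
  # architectures rather than one shared one with uncorrelated weights.
  causal1 <- sample.int(blk$M, m)
  causal2 <- if (rgt == 0) sample.int(blk$M, m) else causal1
  eff <- draw_effects(m, h1t, h2t, rgt)
  zz <- tryCatch({
    if (scenario$mode == "direct") {
      mu_noise <- simulate_sumstats_fixed2(blk, causal1, causal2,
                                           eff$beta1, eff$beta2,
                                           scenario$N1, scenario$N2)
      mu_noise
    } else {
      X1 <- simulate_genotypes(scenario$N1, blk)
      X2 <- simulate_genotypes(scenario$N2, blk)
      y1 <- simulate_phenotypes(X1, causal1, eff$beta1, h1t)
      y2 <- simulate_phenotypes(X2, causal2, eff$beta2, h2t)
      list(z1 = gwas_zscores(X1, y1), z2 = gwas_zscores(X2, y2))
    }
  }, error = function(e) e)
  base <- data.frame(h1_true = h1t, h2_true = h2t, rg_true = rgt,
                     m_causal = m, replicate = rep_i, seed = sd_i,
                     stringsAsFactors = FALSE)
  per_r0 <- lapply(r0_list, function(r0) {
    if (inherits(zz, "error")) {
      cbind(base, data.frame(r0 = r0, h1_hat = NA, h2_hat = NA,
                             h12_hat = NA, rg_hat = NA, lambda = NA,
                             pvalue = NA, ci_low = NA, ci_high = NA,
                             flags = paste0("sim_error:", conditionMessage(zz))))
    } else {
      res <- tryCatch(
        hdlc_test(blk, zz$z1, zz$z2, scenario$N1, scenario$N2, r0 = r0,
                  compute_ci = compute_ci),
        error = function(e) e)
      if (inherits(res, "error")) {
        cbind(base, data.frame(r0 = r0, h1_hat = NA, h2_hat = NA,
                               h12_hat = NA, rg_hat = NA, lambda = NA,
                               pvalue = NA, ci_low = NA, ci_high = NA,
                               flags = paste0("fit_error:", conditionMessage(res))))
      } else {
        cbind(base, data.frame(r0 = r0, h1_hat = res$h1_hat,
                               h2_hat = res$h2_hat, h12_hat = res$h12_hat,
                               rg_hat = res$rg_hat, lambda = res$lambda,
                               pvalue = res$pvalue, ci_low = res$rg_ci_low,
                               ci_high = res$rg_ci_high,
                               flags = paste(res$flags, collapse = ";")))
      }
    }
  })
  do.call(rbind, per_r0)
}
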