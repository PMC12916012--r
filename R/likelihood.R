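## Eigen-space likelihood of regional Z-scores.
##
## Model: stacked Z-score vector (z1, z2) ~ N(0, Sigma) with
##   Sigma_ii = (N_i h_i^2 / M) L + R,   Sigma_12 = (sqrt(N1 N2) h12 / M) L,
## where R is the LD correlation matrix and L = R %*% R. Writing
## R = U diag(lambda) U', both L and R diagonalize in U, so for each
## retained eigenvalue lambda_k the projected pair (u_k' z1, u_k' z2) is an
## independent bivariate normal with covariance
##   [ N1 h1^2 lambda^2 / M + lambda ,  sqrt(N1 N2) h12 lambda^2 / M ]
##   [            .                 ,  N2 h2^2 lambda^2 / M + lambda ].
## The log-likelihood is the sum of K bivariate normal log-densities;
## truncated eigen-directions are omitted.

# Per-eigenvalue model constants for one region / trait pair.
.eig_terms <- function(block, z1, z2 = NULL, N1, N2 = NULL) {
  if (length(z1) != block$M)
    stop("z vector length does not match the LD block")
  out <- list(lam = block$eigvals,
              a1 = N1 * block$eigvals^2 / block$M,
              w1 = drop(crossprod(block$eigvecs, z1)))
  if (!is.null(z2)) {
    if (length(z2) != block$M)
      stop("z vector length does not match the LD block")
    out$a2 <- N2 * block$eigvals^2 / block$M
    out$b <- sqrt(N1 * N2) * block$eigvals^2 / block$M
    out$w2 <- drop(crossprod(block$eigvecs, z2))
  }
  out
}

#' Joint log-likelihood of two traits' regional Z-scores
#'
#' Evaluates the log-density of the stacked vector `(z1, z2)` under the
#' bivariate Gaussian summary-statistics model with within-trait covariance
#' `(N_i h_i^2 / M) L + R` and cross-trait covariance
#' `(sqrt(N1 N2) h12 / M) L`, computed in the eigen-space of `R` (one 2x2
#' bivariate normal per retained eigenvalue). Directions truncated from the
#' block are omitted from the likelihood.
#'
#' @param block An [ld_block()].
#' @param z1,z2 Z-score vectors in `block$variant_ids` order.
#' @param N1,N2 GWAS sample sizes.
#' @param h1_sq,h2_sq Local SNP heritabilities (`>= 0`).
#' @param h12 Local genetic covariance; must satisfy
#'   `|h12| <= sqrt(h1_sq * h2_sq)`.
#' @return Scalar log-likelihood; `-Inf` (with a warning) if a per-
#'   eigenvalue 2x2 covariance fails positive definiteness at numerically
#'   extreme parameter values.
#' @export
loglik_joint <- function(block, z1, z2, N1, N2, h1_sq, h2_sq, h12) {
  if (h1_sq < 0 || h2_sq < 0) stop("heritabilities must be >= 0")
  if (abs(h12) > sqrt(h1_sq * h2_sq) + 1e-12)
    stop("|h12| exceeds sqrt(h1_sq * h2_sq)")
  tm <- .eig_terms(block, z1, z2, N1, N2)
  .ll_h12(h12, tm, h1_sq, h2_sq)
}

# loglik over the per-eigenvalue terms with h1, h2 fixed; used by every
# profiling routine so the O(K) inner loop lives in one place.
.ll_h12 <- function(h12, tm, h1_sq, h2_sq) {
  s1 <- tm$a1 * h1_sq + tm$lam
  s2 <- tm$a2 * h2_sq + tm$lam
  cc <- tm$b * h12
  d <- s1 * s2 - cc^2
  if (any(s1 <= 0) || any(d <= 0)) {
    warning("non-positive-definite 2x2 covariance block; loglik = -Inf")
    return(-Inf)
  }
  q <- (s2 * tm$w1^2 - 2 * cc * tm$w1 * tm$w2 + s1 * tm$w2^2) / d
  sum(-log(2 * pi) - 0.5 * log(d) - 0.5 * q)
}

# first/second derivative of .ll_h12 in h12
.ll_h12_grad <- function(h12, tm, h1_sq, h2_sq) {
  s1 <- tm$a1 * h1_sq + tm$lam
  s2 <- tm$a2 * h2_sq + tm$lam
  cc <- tm$b * h12
  d <- s1 * s2 - cc^2
  n <- s2 * tm$w1^2 - 2 * cc * tm$w1 * tm$w2 + s1 * tm$w2^2
  dp <- -2 * tm$b * cc            # d'
  np <- -2 * tm$b * tm$w1 * tm$w2 # n'
  dpp <- -2 * tm$b^2              # d''
  g <- sum(-0.5 * dp / d - 0.5 * (np * d - n * dp) / d^2)
  h <- sum(-0.5 * (dpp * d - dp^2) / d^2 + 0.5 * n * dpp / d^2 +
             dp * (np * d - n * dp) / d^3)
  list(g = g, h = h)
}

# single-trait marginal: w_k ~ N(0, a_k h^2 + lam_k)
.ll_h2 <- function(h_sq, tm) {
  s <- tm$a1 * h_sq + tm$lam
  if (any(s <= 0)) return(-Inf)
  sum(-0.5 * (log(2 * pi * s) + tm$w1^2 / s))
}

.ll_h2_grad <- function(h_sq, tm) {
  s <- tm$a1 * h_sq + tm$lam
  list(g = 0.5 * sum(tm$a1 * (tm$w1^2 - s) / s^2),
       h = 0.5 * sum(tm$a1^2 * (s - 2 * tm$w1^2) / s^3))
}

# Safeguarded 1-D Newton maximization on [lower, upper]: coarse-grid start,
# Newton steps projected into the interval, golden-section fallback
# (stats::optimize) if curvature is non-negative or Newton stalls.
# Convergence is declared on the parameter step (|step| < tol) or at a
# boundary with the gradient pointing outward.
.newton_bounded <- function(ll, grad, lower, upper, grid,
                            tol = 1e-6, max_iter = 100L) {
  vals <- vapply(grid, ll, 0)
  x <- grid[which.max(vals)]
  converged <- FALSE
  used_fallback <- FALSE
  it <- 0L
  g <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    gh <- grad(x)
    g <- gh$g
    if ((x <= lower && g < 0) || (x >= upper && g > 0)) {
      converged <- TRUE  # boundary optimum: gradient points outside
      break
    }
    if (!is.finite(gh$h) || gh$h >= 0) { used_fallback <- TRUE; break }
    step <- -g / gh$h
    x_new <- min(max(x + step, lower), upper)
    if (abs(x_new - x) < tol) { x <- x_new; converged <- TRUE; break }
    # require ascent; otherwise hand over to the bracketing fallback
    if (ll(x_new) < ll(x) - 1e-12) { used_fallback <- TRUE; break }
    x <- x_new
  }
  if (!converged && (used_fallback || it >= max_iter)) {
    if (upper > lower) {
      opt <- stats::optimize(ll, c(lower, upper), maximum = TRUE,
                             tol = min(tol, 1e-8))
      cand <- c(opt$maximum, lower, upper, x)
      x <- cand[which.max(vapply(cand, ll, 0))]
      g <- grad(x)$g
      converged <- TRUE
    }
  }
  boundary <- x <= lower + tol | x >= upper - tol
  list(x = x, loglik = ll(x), iterations = it, converged = converged,
       boundary = boundary, grad_norm = abs(g), fallback = used_fallback)
}

.fit_report <- function(opt) {
  list(loglik = opt$loglik, iterations = opt$iterations,
       converged = opt$converged, boundary = opt$boundary,
       grad_norm = opt$grad_norm, fallback = opt$fallback)
}

#' Maximum-likelihood local heritability for one trait
#'
#' Maximizes the single-trait marginal likelihood of the regional Z-scores
#' (each projected coordinate `u_k' z` is `N(0, N h^2 lambda_k^2 / M +
#' lambda_k)`) over `h^2` in `[0, 1]`. Newton-Raphson with analytic
#' derivatives and step tolerance `1e-6`, safeguarded by golden-section
#' search when the Newton step leaves the interval or the curvature is not
#' negative. Boundary solutions (`h^2 = 0` in regions without signal) are
#' legitimate and flagged in the report.
#'
#' @inheritParams loglik_joint
#' @param z Z-score vector in block order.
#' @param N GWAS sample size (scalar).
#' @param tol Convergence tolerance on the parameter step.
#' @param max_iter Maximum Newton iterations.
#' @return List with `h2_hat` and `report` (`loglik`, `iterations`,
#'   `converged`, `boundary`, `grad_norm`).
#' @export
fit_h2 <- function(block, z, N, tol = 1e-6, max_iter = 100L) {
  tm <- .eig_terms(block, z, N1 = N)
  grid <- c(0, 10^seq(-6, 0, length.out = 30))
  opt <- .newton_bounded(function(h) .ll_h2(h, tm),
                         function(h) .ll_h2_grad(h, tm),
                         lower = 0, upper = 1, grid = grid,
                         tol = tol, max_iter = max_iter)
  if (!opt$converged)
    stop(sprintf("heritability fit did not converge (%d iterations, |grad| = %g)",
                 opt$iterations, opt$grad_norm))
  list(h2_hat = opt$x, report = .fit_report(opt))
}

#' Profile log-likelihood of the local genetic covariance
#'
#' The joint log-likelihood with the heritabilities held at their
#' single-trait maximum-likelihood estimates, as a function of the genetic
#' covariance `h12` alone.
#'
#' @inheritParams loglik_joint
#' @param h12 Genetic covariance at which to evaluate; must satisfy
#'   `|h12| <= sqrt(h1_hat * h2_hat)` (up to rounding).
#' @param h1_hat,h2_hat Fixed heritability estimates.
#' @return Scalar profile log-likelihood.
#' @export
profile_loglik_h12 <- function(h12, h1_hat, h2_hat, block, z1, z2, N1, N2) {
  bound <- sqrt(h1_hat * h2_hat)
  if (abs(h12) > bound + 1e-12)
    stop("h12 outside the admissible interval")
  tm <- .eig_terms(block, z1, z2, N1, N2)
  .ll_h12(min(max(h12, -bound), bound), tm, h1_hat, h2_hat)
}

#' Constrained maximum of the covariance profile likelihood
#'
#' Maximizes the profile log-likelihood of `h12` (heritabilities fixed at
#' `h1_hat`, `h2_hat`) over the interval `|h12| <= bound`, by safeguarded
#' Newton-Raphson with analytic derivatives (step tolerance `1e-6`) and a
#' bracketing fallback. The optimum may be interior or on the boundary; the
#' report flags which.
#'
#' @inheritParams profile_loglik_h12
#' @param bound Non-negative half-width of the admissible interval, e.g.
#'   `sqrt(h1_hat * h2_hat)` for the free fit or `r0 * sqrt(h1_hat *
#'   h2_hat)` for the constrained fit.
#' @param tol,max_iter Newton controls as in [fit_h2()].
#' @return List with `h12_hat` and `report`.
#' @export
fit_h12 <- function(h1_hat, h2_hat, block, z1, z2, N1, N2, bound,
                    tol = 1e-6, max_iter = 100L) {
  if (bound < 0) stop("bound must be >= 0")
  tm <- .eig_terms(block, z1, z2, N1, N2)
  if (bound == 0) {
    ll0 <- .ll_h12(0, tm, h1_hat, h2_hat)
    return(list(h12_hat = 0,
                report = list(loglik = ll0, iterations = 0L,
                              converged = TRUE, boundary = TRUE,
                              grad_norm = NA_real_, fallback = FALSE)))
  }
  grid <- bound * seq(-1, 1, length.out = 41)
  opt <- .newton_bounded(function(h) .ll_h12(h, tm, h1_hat, h2_hat),
                         function(h) .ll_h12_grad(h, tm, h1_hat, h2_hat),
                         lower = -bound, upper = bound, grid = grid,
                         tol = tol * max(bound, 1), max_iter = max_iter)
  if (!opt$converged)
    stop(sprintf("covariance fit did not converge (%d iterations, |grad| = %g)",
                 opt$iterations, opt$grad_norm))
  list(h12_hat = opt$x, report = .fit_report(opt))
}
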