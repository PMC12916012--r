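test_that("eigen-space likelihood equals the dense Gaussian oracle", {
  set.seed(11)
  for (i in 1:20) {
    M <- sample(5:20, 1)
    blk <- simulate_ld_ar1(M, runif(1, -0.9, 0.9))
    h1 <- runif(1, 0, 0.3); h2 <- runif(1, 0, 0.3)
    h12 <- runif(1, -1, 1) * sqrt(h1 * h2)
    N1 <- runif(1, 1e3, 1e5); N2 <- runif(1, 1e3, 1e5)
    zz <- simulate_sumstats_direct(blk, h1, h2, h12, N1, N2)
    expect_equal(loglik_joint(blk, zz$z1, zz$z2, N1, N2, h1, h2, h12),
                 dense_loglik(blk, zz$z1, zz$z2, N1, N2, h1, h2, h12),
                 tolerance = 1e-10)
  }
})

test_that("null parameters reduce to two independent N(0, R) factors", {
  set.seed(4)
  blk <- simulate_ld_ar1(15, 0.6)
  zz <- simulate_sumstats_direct(blk, 0, 0, 0, 1e4, 1e4)
  single <- function(z) {
    w <- drop(crossprod(blk$eigvecs, z))
    sum(-0.5 * (log(2 * pi * blk$eigvals) + w^2 / blk$eigvals))
  }
  expect_equal(loglik_joint(blk, zz$z1, zz$z2, 1e4, 1e4, 0, 0, 0),
               single(zz$z1) + single(zz$z2))
})

test_that("likelihood is invariant to joint allele flips and permutations", {
  set.seed(5)
  blk <- simulate_ld_ar1(12, 0.7)
  zz <- simulate_sumstats_direct(blk, 0.1, 0.1, 0.05, 1e4, 1e4)
  base <- loglik_joint(blk, zz$z1, zz$z2, 1e4, 1e4, 0.1, 0.1, 0.05)

  # flip variant j: negate z1_j, z2_j and row/column j of R
  j <- 5
  Rf <- blk$R; Rf[j, ] <- -Rf[j, ]; Rf[, j] <- -Rf[, j]
  z1f <- zz$z1; z1f[j] <- -z1f[j]
  z2f <- zz$z2; z2f[j] <- -z2f[j]
  expect_equal(loglik_joint(ld_block(Rf), z1f, z2f, 1e4, 1e4, 0.1, 0.1, 0.05),
               base, tolerance = 1e-8)

  # joint permutation
  p <- sample(blk$M)
  expect_equal(loglik_joint(ld_block(blk$R[p, p]), zz$z1[p], zz$z2[p],
                            1e4, 1e4, 0.1, 0.1, 0.05),
               base, tolerance = 1e-8)
})

test_that("loglik_joint rejects out-of-domain parameters", {
  blk <- simulate_ld_ar1(5, 0.5)
  z <- rep(0, 5)
  expect_error(loglik_joint(blk, z, z, 100, 100, -0.1, 0.1, 0), ">= 0")
  expect_error(loglik_joint(blk, z, z, 100, 100, 0.1, 0.1, 0.2), "exceeds")
})

test_that("fit_h2 agrees with a dense grid search", {
  set.seed(21)
  for (i in 1:8) {
    blk <- simulate_ld_ar1(sample(20:50, 1), runif(1, 0.2, 0.9))
    h_true <- runif(1, 0, 0.4)
    zz <- simulate_sumstats_direct(blk, h_true, 0, 0, 5e4, 5e4)
    fit <- fit_h2(blk, zz$z1, 5e4)
    tm <- hdlc:::.eig_terms(blk, zz$z1, N1 = 5e4)
    best <- grid_argmax(function(h) hdlc:::.ll_h2(h, tm), 0, 0.5, 5001)
    expect_lt(abs(fit$h2_hat - best), 1e-4 + 1e-9)
    expect_true(fit$report$converged)
  }
})

test_that("fit_h2 recovers truth on average and flags null boundaries", {
  blk <- simulate_ld_ar1(200, 0.9)
  est <- vapply(1:200, function(i) {
    zz <- simulate_sumstats_direct(blk, 0.05, 0, 0, 5e4, 5e4, seed = 900 + i)
    fit_h2(blk, zz$z1, 5e4)$h2_hat
  }, 0)
  expect_lt(abs(mean(est) - 0.05), 0.01)

  # true h2 = 0: estimates pile up at the boundary
  null_fit <- lapply(1:20, function(i) {
    zz <- simulate_sumstats_direct(blk, 0, 0, 0, 5e4, 5e4, seed = 300 + i)
    fit_h2(blk, zz$z1, 5e4)
  })
  h0 <- vapply(null_fit, `[[`, 0, "h2_hat")
  expect_lt(mean(h0), 0.005)
  expect_true(any(vapply(null_fit, function(f) f$report$boundary, TRUE)))
})

test_that("profile likelihood behaves on its closed interval", {
  set.seed(31)
  blk <- simulate_ld_ar1(30, 0.8)
  zz <- simulate_sumstats_direct(blk, 0.1, 0.1, 0.06, 2e4, 2e4)
  f1 <- fit_h2(blk, zz$z1, 2e4)$h2_hat
  f2 <- fit_h2(blk, zz$z2, 2e4)$h2_hat
  bound <- sqrt(f1 * f2)

  # h12 = 0 equals the joint likelihood at zero covariance
  expect_equal(profile_loglik_h12(0, f1, f2, blk, zz$z1, zz$z2, 2e4, 2e4),
               loglik_joint(blk, zz$z1, zz$z2, 2e4, 2e4, f1, f2, 0))
  expect_error(profile_loglik_h12(bound * 1.01, f1, f2, blk, zz$z1, zz$z2,
                                  2e4, 2e4), "admissible")

  # continuous, attains its max: dense scan is finite everywhere
  xs <- seq(-bound, bound, length.out = 201)
  vals <- vapply(xs, profile_loglik_h12, 0, h1_hat = f1, h2_hat = f2,
                 block = blk, z1 = zz$z1, z2 = zz$z2, N1 = 2e4, N2 = 2e4)
  expect_true(all(is.finite(vals)))

  # symmetric data: profile maximized at the upper bound
  fs <- fit_h2(blk, zz$z1, 2e4)$h2_hat
  fit_sym <- fit_h12(fs, fs, blk, zz$z1, zz$z1, 2e4, 2e4, bound = fs)
  expect_equal(fit_sym$h12_hat, fs, tolerance = 1e-6)
  expect_true(fit_sym$report$boundary)
})

test_that("fit_h12 agrees with a dense grid search and honors bounds", {
  set.seed(41)
  for (i in 1:8) {
    blk <- simulate_ld_ar1(sample(20:50, 1), runif(1, 0.2, 0.9))
    h1 <- runif(1, 0.02, 0.3); h2 <- runif(1, 0.02, 0.3)
    h12 <- runif(1, -0.9, 0.9) * sqrt(h1 * h2)
    zz <- simulate_sumstats_direct(blk, h1, h2, h12, 5e4, 5e4)
    f1 <- fit_h2(blk, zz$z1, 5e4)$h2_hat
    f2 <- fit_h2(blk, zz$z2, 5e4)$h2_hat
    bound <- sqrt(f1 * f2)
    if (bound == 0) next
    fit <- fit_h12(f1, f2, blk, zz$z1, zz$z2, 5e4, 5e4, bound = bound)
    tm <- hdlc:::.eig_terms(blk, zz$z1, zz$z2, 5e4, 5e4)
    best <- grid_argmax(function(h) hdlc:::.ll_h12(h, tm, f1, f2),
                        -bound, bound, 4001)
    expect_lt(abs(fit$h12_hat - best), 2 * bound / 4000 + 1e-9)

    # degenerate interval
    expect_identical(fit_h12(f1, f2, blk, zz$z1, zz$z2, 5e4, 5e4,
                             bound = 0)$h12_hat, 0)
    # KKT: shrinking the bound below the free optimum lands on the boundary
    if (abs(fit$h12_hat) > 1e-4) {
      small <- abs(fit$h12_hat) / 2
      cfit <- fit_h12(f1, f2, blk, zz$z1, zz$z2, 5e4, 5e4, bound = small)
      expect_equal(abs(cfit$h12_hat), small, tolerance = 1e-6)
    }
  }
})

test_that("profile maximum is monotone in the interval width", {
  set.seed(51)
  blk <- simulate_ld_ar1(40, 0.7)
  zz <- simulate_sumstats_direct(blk, 0.1, 0.1, 0.08, 3e4, 3e4)
  f1 <- fit_h2(blk, zz$z1, 3e4)$h2_hat
  f2 <- fit_h2(blk, zz$z2, 3e4)$h2_hat
  bound <- sqrt(f1 * f2)
  lls <- vapply(c(0.25, 0.5, 1) * bound, function(b)
    fit_h12(f1, f2, blk, zz$z1, zz$z2, 3e4, 3e4, bound = b)$report$loglik, 0)
  expect_true(all(diff(lls) >= -1e-9))
})
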