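test_that("draw_effects hits its target covariance", {
  # degenerate correlation: exact proportionality
  eff <- draw_effects(50, 0.1, 0.4, 1, seed = 1)
  expect_equal(eff$beta2, 2 * eff$beta1)

  # independence at rG = 0
  eff0 <- draw_effects(10000, 0.1, 0.1, 0, seed = 2)
  expect_lt(abs(cor(eff0$beta1, eff0$beta2)), 0.03)

  # Monte-Carlo moment check of the full 2x2 covariance
  m <- 50000
  eff2 <- draw_effects(m, 0.2, 0.05, 0.6, seed = 3)
  emp <- cov(cbind(eff2$beta1, eff2$beta2)) * m
  target <- matrix(c(0.2, 0.6 * sqrt(0.2 * 0.05),
                     0.6 * sqrt(0.2 * 0.05), 0.05), 2)
  expect_lt(max(abs(emp - target) / abs(target)), 0.05)
  expect_error(draw_effects(10, 0.1, 0.1, 1.2), "rG")
})

test_that("simulated genotypes reproduce the LD matrix", {
  blk <- simulate_ld_ar1(50, 0.8)
  X <- simulate_genotypes(20000, blk, seed = 4)
  expect_equal(dim(X), c(20000, 50))
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_lt(max(abs(cor(X) - blk$R)), 0.05)

  # identity LD: empirical correlations near zero
  Xi <- simulate_genotypes(3000, ld_block(diag(10)), seed = 5)
  off <- cor(Xi); diag(off) <- 0
  expect_lt(max(abs(off)), 0.06)

  # reproducibility
  expect_identical(simulate_genotypes(100, blk, seed = 6),
                   simulate_genotypes(100, blk, seed = 6))
})

test_that("phenotypes have unit variance and linear genetic structure", {
  blk <- simulate_ld_ar1(30, 0.5)
  X <- simulate_genotypes(2000, blk, seed = 7)

  # h2 = 0, beta = 0: pure noise with variance 1
  y0 <- simulate_phenotypes(X, integer(0), numeric(0), 0, seed = 8)
  expect_lt(abs(var(y0) - 1), 0.1)

  # variance centred near 1 across replicates at h2 = 0.1
  v <- vapply(1:200, function(i) {
    eff <- draw_effects(3, 0.1, 0.1, 0)
    var(simulate_phenotypes(X, 1:3, eff$beta1, 0.1))
  }, 0)
  expect_lt(abs(mean(v) - 1), 0.05)

  # doubling beta doubles the genetic component exactly
  beta <- c(0.1, -0.2)
  set.seed(9); y1 <- simulate_phenotypes(X, 1:2, beta, 0.05)
  set.seed(9); y2 <- simulate_phenotypes(X, 1:2, 2 * beta, 0.05)
  g <- drop(X[, 1:2] %*% beta)
  expect_equal(y2 - y1, g)
  expect_error(simulate_phenotypes(X, 1:2, beta, 1), "h_sq")
})

test_that("gwas_zscores is the marginal-regression t-statistic", {
  blk <- simulate_ld_ar1(100, 0.6)
  X <- simulate_genotypes(10000, blk, seed = 10)

  # null calibration: mean z^2 near 1
  y <- rnorm(10000)
  z <- gwas_zscores(X, y)
  expect_lt(abs(mean(z^2) - 1), 0.15)

  # agreement with lm() on a few columns
  for (j in c(1, 50)) {
    co <- summary(lm(y ~ X[, j]))$coefficients
    expect_equal(z[j], co[2, "t value"], tolerance = 1e-6)
  }

  # degenerate: y equal to a column gives a huge finite z
  zd <- gwas_zscores(X, X[, 3])
  expect_true(is.finite(zd[3]) && abs(zd[3]) > 1e5)
})

test_that("direct sampler matches the model's second moments and seeds", {
  blk <- simulate_ld_ar1(30, 0.7)
  Z <- vapply(1:800, function(i)
    simulate_sumstats_direct(blk, 0, 0, 0, 1e4, 1e4, seed = 100 + i)$z1,
    numeric(30))
  emp <- tcrossprod(Z) / 800
  expect_lt(max(abs(emp - blk$R)), 0.25)
  expect_lt(abs(mean(diag(emp)) - 1), 0.1)

  s1 <- simulate_sumstats_direct(blk, 0.1, 0.1, 0.05, 1e4, 1e4, seed = 12)
  s2 <- simulate_sumstats_direct(blk, 0.1, 0.1, 0.05, 1e4, 1e4, seed = 12)
  expect_identical(s1, s2)
  expect_error(simulate_sumstats_direct(blk, 0.01, 0.01, 0.02, 1e4, 1e4),
               "exceeds")
})

test_that("individual-level and direct modes give concordant statistics", {
  # same grid point through both pipelines; Lambda distributions should
  # agree (individual-level N kept modest for runtime)
  blk <- simulate_ld_ar1(40, 0.8)
  sc_args <- list(block = blk, causal_fraction = 0.1, h1_source = 0.15,
                  h2_grid = 0.15, rg_grid = 0.8, N1 = 3000, N2 = 3000,
                  n_replicates = 60)
  direct <- run_scenario(do.call(sim_scenario,
                                 c(sc_args, mode = "direct", seed = 21)),
                         r0_list = 0)
  indiv <- run_scenario(do.call(sim_scenario,
                                c(sc_args, mode = "individual", seed = 22)),
                        r0_list = 0)
  ks <- suppressWarnings(ks.test(direct$lambda, indiv$lambda))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_scenario is reproducible, complete, and resumable", {
  blk <- simulate_ld_ar1(30, 0.6)
  sc <- sim_scenario(blk, causal_fraction = 0.1, h1_source = 0.1,
                     h2_grid = c(0.01, 0.1), rg_grid = c(0, 1),
                     N1 = 1e4, N2 = 1e4, n_replicates = 3, seed = 77)
  t1 <- run_scenario(sc, r0_list = c(0, 0.5))
  expect_equal(nrow(t1), 2 * 2 * 3 * 2)  # grid x replicates x r0
  t2 <- run_scenario(sc, r0_list = c(0, 0.5))
  expect_equal(t1, t2)

  # resume: pre-write half the cells, only the rest are recomputed
  f <- tempfile(fileext = ".tsv")
  half <- t1[t1$h2_true == 0.01, ]
  data.table::fwrite(half, f, sep = "\t")
  t3 <- run_scenario(sc, r0_list = c(0, 0.5), out_tsv = f)
  expect_equal(nrow(t3), nrow(t1))
  expect_setequal(unique(t3$h2_true), c(0.01, 0.1))
})

test_that("single-causal grids with rG in {0, -1, 1} run end to end", {
  blk <- simulate_ld_ar1(50, 0.9)
  sc <- sim_scenario(blk, causal_count = 1, h1_source = "standin",
                     h2_grid = 1e-3, rg_grid = c(0, -1, 1),
                     N1 = 3e4, N2 = 3e5, n_replicates = 2, seed = 5)
  tab <- run_scenario(sc, r0_list = 0)
  expect_equal(nrow(tab), 6)
  expect_true(all(is.finite(tab$pvalue)))
})

test_that("the top-variant heritability stand-in stays in range", {
  x <- top_h2_standin(5000, seed = 30)
  expect_true(all(x >= 0.001 & x <= 0.5))
  expect_gt(median(x), 0.01)
  expect_lt(median(x), 0.15)
})
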