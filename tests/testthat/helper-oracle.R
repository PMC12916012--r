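# Independent brute-force oracle: log-density of the stacked Z-score
# vector under the dense 2M x 2M Gaussian, assembled directly from the
# model's covariance blocks and evaluated via the Cholesky factor. Shares
# no code with the package's eigen-space path.
dense_loglik <- function(blk, z1, z2, N1, N2, h1, h2, h12) {
  S11 <- N1 * h1 / blk$M * blk$L + blk$R
  S22 <- N2 * h2 / blk$M * blk$L + blk$R
  S12 <- sqrt(N1 * N2) * h12 / blk$M * blk$L
  S <- rbind(cbind(S11, S12), cbind(S12, S22))
  z <- c(z1, z2)
  ch <- chol(S)
  -0.5 * (2 * sum(log(diag(ch))) +
            sum(backsolve(ch, z, transpose = TRUE)^2) +
            2 * blk$M * log(2 * pi))
}

# grid-search oracle for a 1-D maximization
grid_argmax <- function(f, lower, upper, n = 2001) {
  xs <- seq(lower, upper, length.out = n)
  xs[which.max(vapply(xs, f, 0))]
}

# small sumstats fixture with alleles and positions
toy_sumstats <- function() {
  sumstats(id = paste0("rs", 1:6),
           z = c(1.2, -0.4, 2.5, 0.3, -1.8, 0.9),
           n = 10000,
           chrom = rep("1", 6),
           pos = c(5e5, 9e5, 1.2e6, 1.9e6, 2.6e6, 3.4e6),
           ea = c("A", "C", "G", "T", "A", "C"),
           oa = c("G", "T", "A", "C", "T", "G"),
           maf = c(0.30, 0.05, 0.049, 0.20, 0.45, 0.10),
           trait_label = "toy")
}
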