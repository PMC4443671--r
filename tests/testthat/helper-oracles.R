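# Independent oracles and fixture generators used across the suite.

# Dense multivariate-normal log density via solve()/determinant(): an
# implementation-independent check of the Cholesky-based marginal likelihood.
dense_mvn_logpdf <- function(y, C) {
  J <- length(y)
  ld <- determinant(C, logarithm = TRUE)
  -0.5 * drop(t(y) %*% solve(C, y)) - 0.5 * as.numeric(ld$modulus) -
    0.5 * J * log(2 * pi)
}

# Brute-force conditional-Gaussian prediction oracle.
dense_gp_predict <- function(t_star, t, y, kernel, C) {
  Ks <- se_covariance(t_star, t, kernel$length_scale, kernel$signal_variance)
  Kss <- se_covariance(t_star, t_star, kernel$length_scale, kernel$signal_variance)
  Ci <- solve(C)
  list(mean = drop(Ks %*% Ci %*% y), cov = Kss - Ks %*% Ci %*% t(Ks))
}

# Random well-conditioned covariance and data for likelihood checks.
random_gp_instance <- function(J) {
  t <- sort(runif(J, 0, 60))
  kernel <- list(length_scale = runif(1, 5, 40),
                 signal_variance = runif(1, 0.01, 1))
  fbb <- runif(J, 1e-4, 0.05)
  sn2 <- runif(1, 1e-4, 0.1)
  C <- assemble_covariance(t, kernel, sn2, fbb)
  y <- drop(t(chol(C)) %*% rnorm(J))
  list(t = t, y = y, kernel = kernel, sn2 = sn2, fbb = fbb, C = C)
}

# One SNP's observations with binomial reads around a frequency trajectory
# freq_fun(gen) shared by all replicates; Poisson(lambda) depth.
make_snp_series <- function(gens = c(0, 14, 28, 44, 60), reps = 5,
                            freq_fun = function(g) 0.5, lambda = 45,
                            snp_id = "s1") {
  obs <- tidyr::expand_grid(gen = gens, replicate = seq_len(reps))
  obs$n <- stats::rpois(nrow(obs), lambda)
  obs$y <- stats::rbinom(nrow(obs), obs$n, freq_fun(obs$gen))
  obs$snp_id <- snp_id
  obs
}

# Many null SNPs (constant but SNP-specific frequency) in one tidy table.
make_null_table <- function(n_snps, gens = c(0, 14, 28, 44, 60), reps = 5,
                            lambda = 45) {
  purrr::map_dfr(seq_len(n_snps), function(i) {
    p <- stats::runif(1, 0.2, 0.8)
    make_snp_series(gens, reps, function(g) p, lambda,
                    snp_id = sprintf("null%04d", i))
  })
}

# Replicate-stratified null 2x2 tables from a common frequency.
make_null_tables <- function(R = 5, p = NULL, lambda = 45) {
  if (is.null(p)) p <- stats::runif(1, 0.2, 0.8)
  nB <- stats::rpois(R, lambda); nE <- stats::rpois(R, lambda)
  yB <- stats::rbinom(R, nB, p); yE <- stats::rbinom(R, nE, p)
  lapply(seq_len(R), function(r) {
    matrix(c(yB[r], nB[r] - yB[r], yE[r], nE[r] - yE[r]), nrow = 2)
  })
}
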