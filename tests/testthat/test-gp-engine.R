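test_that("squared-exponential covariance has the right limits", {
  expect_equal(se_covariance(3, 3, length_scale = 10, signal_variance = 0.05),
               matrix(0.05))
  expect_equal(se_covariance(0, 10 * sqrt(2), length_scale = 10,
                             signal_variance = 1),
               matrix(exp(-1)))
  # constant-function limit for a very long length scale
  t <- c(0, 20, 60)
  K <- se_covariance(t, t, length_scale = 1e6, signal_variance = 0.3)
  expect_equal(K, matrix(0.3, 3, 3), tolerance = 1e-8)
  expect_error(se_covariance(t, t, length_scale = 0, signal_variance = 1),
               "positive")
})

test_that("assembled covariance sums kernel, white noise and FBB terms", {
  expect_equal(assemble_covariance(c(0, 10), kernel = NULL,
                                   noise_variance = 0, fbb = c(0.1, 0.2)),
               diag(c(0.1, 0.2)))
  C1 <- assemble_covariance(5, kernel = list(length_scale = 3,
                                             signal_variance = 0.4),
                            noise_variance = 0.2, fbb = 0.1)
  expect_equal(C1, matrix(0.7))
  # replicates at the same time share the full signal covariance
  C2 <- assemble_covariance(c(0, 0), kernel = list(length_scale = 5,
                                                   signal_variance = 0.3),
                            noise_variance = 0.01, fbb = c(0.1, 0.1))
  expect_equal(C2[1, 2], 0.3)
  expect_error(assemble_covariance(c(0, 1), NULL, 0, fbb = c(1, 2, 3)),
               "per time point")
})

test_that("log marginal likelihood matches univariate and dense oracles", {
  expect_equal(gp_log_marginal(0, matrix(2.5)), -0.5 * log(2 * pi * 2.5))
  expect_equal(gp_log_marginal(1, matrix(1)), dnorm(1, log = TRUE))
  expect_equal(gp_log_marginal(c(1, -1), diag(2)),
               sum(dnorm(c(1, -1), log = TRUE)))
  set.seed(201)
  for (i in 1:100) {
    inst <- random_gp_instance(sample(2:10, 1))
    expect_equal(gp_log_marginal(inst$y, inst$C),
                 dense_mvn_logpdf(inst$y, inst$C), tolerance = 1e-8)
  }
})

test_that("marginal likelihood is invariant under sign flip of the data", {
  set.seed(202)
  inst <- random_gp_instance(8)
  expect_identical(gp_log_marginal(inst$y, inst$C),
                   gp_log_marginal(-inst$y, inst$C))
})

test_that("GP prediction matches the conditional-Gaussian oracle", {
  set.seed(203)
  for (i in 1:20) {
    inst <- random_gp_instance(4)
    t_star <- runif(3, -10, 70)
    got <- gp_predict(t_star, inst$t, inst$y, inst$kernel, inst$C)
    want <- dense_gp_predict(t_star, inst$t, inst$y, inst$kernel, inst$C)
    expect_equal(got$mean, want$mean, tolerance = 1e-10)
    expect_equal(got$cov, want$cov, tolerance = 1e-10)
  }
})

test_that("prediction reverts to the prior far away and interpolates exactly", {
  kernel <- list(length_scale = 5, signal_variance = 0.7)
  t <- c(0, 5, 10); y <- c(0.1, -0.2, 0.1)
  C <- assemble_covariance(t, kernel, noise_variance = 1e-3, fbb = 1e-3)
  far <- gp_predict(1000, t, y, kernel, C)
  expect_equal(far$mean, 0, tolerance = 1e-8)
  expect_equal(drop(far$cov), kernel$signal_variance, tolerance = 1e-8)
  # noise-free interpolation at a training point
  C0 <- assemble_covariance(t, kernel, noise_variance = 0, fbb = 0)
  at <- gp_predict(t[1], t, y, kernel, C0)
  expect_equal(at$mean, y[1], tolerance = 1e-6)
})

test_that("covariances factorise after at most the configured jitter", {
  # rank-deficient: duplicated times, no noise
  t <- c(0, 0, 10, 10)
  C <- assemble_covariance(t, list(length_scale = 5, signal_variance = 1),
                           noise_variance = 0, fbb = 0)
  expect_true(is.finite(gp_log_marginal(c(0.1, 0.1, -0.1, -0.1), C)))
})

test_that("pure white-noise fit recovers the closed-form variance MLE", {
  set.seed(204)
  y <- rnorm(40, 0, 0.3)
  y <- y - mean(y)
  fit <- gp_fit_independent(y, fbb = rep(0, 40) + 1e-12)
  expect_equal(fit$noise_variance, mean(y^2), tolerance = 1e-6)
  # with a constant FBB offset the stationary point shifts by that offset
  c0 <- 0.01
  fit2 <- gp_fit_independent(y, fbb = rep(c0, 40))
  expect_equal(fit2$noise_variance, max(0, mean(y^2) - c0), tolerance = 1e-6)
  # FBB far above the data variance pushes the noise to its floor
  fit3 <- gp_fit_independent(y, fbb = rep(100, 40))
  expect_lt(fit3$noise_variance, 1e-8)
})

test_that("independent fit equals a fine 1-D grid-search oracle", {
  y <- c(-1, 1); fbb <- c(1e-12, 1e-12)
  fit <- gp_fit_independent(y, fbb)
  expect_equal(fit$noise_variance, 1, tolerance = 1e-6)
  expect_equal(fit$log_ml, -1 - log(2 * pi), tolerance = 1e-8)
  set.seed(205)
  y <- rnorm(12, 0, 0.2); y <- y - mean(y)
  fbb <- runif(12, 1e-4, 0.02)
  fit <- gp_fit_independent(y, fbb)
  grid <- exp(seq(log(1e-12), log(1), length.out = 20000))
  oracle <- max(sapply(grid, function(s) {
    sum(dnorm(y, 0, sqrt(s + fbb), log = TRUE))
  }))
  expect_gte(fit$log_ml, oracle - 1e-6)
})

test_that("time-dependent fit never falls below the nested constant model", {
  set.seed(206)
  for (i in 1:25) {
    obs <- make_snp_series(freq_fun = function(g) 0.4)
    prep <- prepare_snp(obs)
    dep <- gp_fit_dependent(prep$t, prep$y_centered, prep$fbb)
    indep <- gp_fit_independent(prep$y_centered, prep$fbb)
    fit <- bbgp_fit_snp(obs)
    expect_gte(fit$ln_bf, -1e-6)
    expect_gte(fit$fit_dep$log_ml, max(dep$log_ml, indep$log_ml) - 1e-6)
  }
})

test_that("length-scale bounds come from distinct time spacings only", {
  b <- bbgptest:::length_scale_bounds(c(0, 0, 14, 14, 60, 60))
  expect_equal(unname(b["lower"]), 14)
  expect_equal(unname(b["upper"]), 600)
  expect_error(bbgptest:::length_scale_bounds(c(5, 5, 5)), "distinct")
})

test_that("fitted length scale respects its lower bound", {
  set.seed(207)
  obs <- make_snp_series(freq_fun = function(g) plogis((g - 30) / 6))
  prep <- prepare_snp(obs)
  fit <- gp_fit_dependent(prep$t, prep$y_centered, prep$fbb)
  expect_gte(fit$length_scale, min(diff(sort(unique(prep$t)))) - 1e-9)
})

test_that("hyperparameters are recovered from GP-simulated data", {
  set.seed(208)
  t_pts <- c(0, 6, 14, 22, 28, 38, 44, 50, 60)
  t <- rep(t_pts, each = 5)
  K <- se_covariance(t_pts, t_pts, length_scale = 15, signal_variance = 0.05)
  ls <- numeric(30)
  for (i in 1:30) {
    f <- drop(t(chol(K + diag(1e-10, 9))) %*% rnorm(9))
    y <- rep(f, each = 5) + rnorm(45, 0, 1e-2)
    y <- y - mean(y)
    ls[i] <- gp_fit_dependent(t, y, rep(1e-12, 45))$length_scale
  }
  expect_gt(median(ls), 15 / 2)
  expect_lt(median(ls), 15 * 2)
})
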