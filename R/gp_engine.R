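# Gaussian-process engine: covariance construction, marginal likelihood via
# Cholesky, posterior prediction, and marginal-likelihood maximisation with
# grid initialisation. Everything here works on plain numeric vectors and
# matrices; the tidy interfaces live in bbgp.R.

SF2_FLOOR <- 1e-12 # signal-variance floor: keeps log-space optimisation finite
SN2_FLOOR <- 1e-12 # white-noise floor, never exactly 0

#' Squared-exponential covariance matrix
#'
#' `K[i, j] = signal_variance * exp(-(t[i] - t_prime[j])^2 / (2 * length_scale^2))`.
#' The length scale (in generations here) sets the distance beyond which two
#' inputs decorrelate; as it grows the kernel approaches the constant
#' function `signal_variance` everywhere.
#'
#' @param t,t_prime Numeric input (time) vectors.
#' @param length_scale Positive length scale.
#' @param signal_variance Non-negative signal variance.
#' @return A `length(t)` by `length(t_prime)` matrix.
#' @export
se_covariance <- function(t, t_prime = t, length_scale, signal_variance) {
  if (length_scale <= 0) abort("`length_scale` must be positive.")
  if (signal_variance < 0) abort("`signal_variance` must be non-negative.")
  d <- outer(t, t_prime, "-")
  signal_variance * exp(-d^2 / (2 * length_scale^2))
}

#' Assemble a model covariance with fixed beta-binomial noise
#'
#' Builds `K_SE(t, t) + noise_variance * I + diag(fbb)`; with `kernel = NULL`
#' the squared-exponential part is omitted (the time-independent model). The
#' `fbb` vector carries the per-observation beta-binomial posterior variances
#' as known, fixed heteroscedastic noise.
#'
#' @param t Time vector.
#' @param kernel `NULL`, or a list with `length_scale` and `signal_variance`.
#' @param noise_variance Non-negative white-noise variance.
#' @param fbb Non-negative variance vector, same length as `t`.
#' @return A symmetric covariance matrix.
#' @export
assemble_covariance <- function(t, kernel = NULL, noise_variance = 0, fbb = 0) {
  J <- length(t)
  fbb <- rep_len(fbb, if (length(fbb) %in% c(1L, J)) J else length(fbb))
  if (length(fbb) != J) abort("`fbb` must have one variance per time point.")
  if (any(fbb < 0) || noise_variance < 0) abort("Variances must be non-negative.")
  K <- if (is.null(kernel)) {
    matrix(0, J, J)
  } else {
    se_covariance(t, t, kernel$length_scale, kernel$signal_variance)
  }
  K + diag(noise_variance + fbb, J)
}

# Cholesky with escalating diagonal jitter: 1e-8 * mean(diag), x10 per retry,
# giving up past 1e-2 * mean(diag).
chol_with_jitter <- function(C) {
  scale <- mean(diag(C))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jitter <- 0
  for (mult in c(0, 10^(-8:-2))) {
    jitter <- mult * scale
    U <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jitter, ok = TRUE))
  }
  list(U = NULL, jitter = jitter, ok = FALSE)
}

#' Gaussian-process log marginal likelihood
#'
#' Log density of a zero-mean multivariate normal with covariance `C`,
#' `-y' C^-1 y / 2 - log|C| / 2 - (J/2) log(2*pi)`, computed through a
#' Cholesky factorisation (never an explicit inverse or determinant). Returns
#' `NA` if the covariance cannot be factorised even after jitter.
#'
#' @param y_centered Centered observation vector.
#' @param C Covariance matrix, same dimension.
#' @return The log marginal likelihood, or `NA_real_` on factorisation failure.
#' @export
gp_log_marginal <- function(y_centered, C) {
  J <- length(y_centered)
  stopifnot(nrow(C) == J, ncol(C) == J)
  fac <- chol_with_jitter(C)
  if (!fac$ok) return(NA_real_)
  z <- forwardsolve(t(fac$U), y_centered)
  -0.5 * sum(z^2) - sum(log(diag(fac$U))) - 0.5 * J * log(2 * pi)
}

# log marginal likelihood and its gradient wrt (log l, log sf2, log sn2).
# D2 is the precomputed squared-distance matrix outer(t,t,"-")^2.
logml_and_grad <- function(theta, D2, y, fbb) {
  l <- exp(theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
  J <- length(y)
  K <- sf2 * exp(-D2 / (2 * l^2))
  C <- K + diag(sn2 + fbb, J)
  fac <- chol_with_jitter(C)
  if (!fac$ok) return(list(value = NA_real_, grad = rep(NA_real_, 3)))
  z <- forwardsolve(t(fac$U), y)
  value <- -0.5 * sum(z^2) - sum(log(diag(fac$U))) - 0.5 * J * log(2 * pi)
  Cinv <- chol2inv(fac$U)
  a <- Cinv %*% y
  A <- tcrossprod(a) - Cinv                      # d logml = 0.5 tr(A dC)
  g_l <- 0.5 * sum(A * (K * D2 / l^2))           # dC/d log l
  g_sf2 <- 0.5 * sum(A * K)                      # dC/d log sf2
  g_sn2 <- 0.5 * sn2 * sum(diag(A))              # dC/d log sn2
  list(value = value, grad = c(g_l, g_sf2, g_sn2))
}

#' GP posterior mean and covariance at new time points
#'
#' Conditional-Gaussian prediction for the latent function:
#' `m* = K(t*, t) C^-1 y` and `S* = K(t*, t*) - K(t*, t) C^-1 K(t, t*)`,
#' where `C` is the training covariance including all noise terms.
#'
#' @param t_star Prediction time points.
#' @param t Training time points.
#' @param y_centered Centered training observations.
#' @param kernel List with `length_scale` and `signal_variance`.
#' @param C Training covariance assembled from the same `t`.
#' @return A list with `mean` (vector) and `cov` (matrix).
#' @export
gp_predict <- function(t_star, t, y_centered, kernel, C) {
  fac <- chol_with_jitter(C)
  if (!fac$ok) abort("Training covariance is not positive definite after jitter.")
  Ks <- se_covariance(t_star, t, kernel$length_scale, kernel$signal_variance)
  Kss <- se_covariance(t_star, t_star, kernel$length_scale, kernel$signal_variance)
  Cinv_y <- backsolve(fac$U, forwardsolve(t(fac$U), y_centered))
  V <- forwardsolve(t(fac$U), t(Ks))
  list(mean = drop(Ks %*% Cinv_y), cov = Kss - crossprod(V))
}

# Length-scale bounds: lower = shortest spacing between *distinct* times
# (replicates at the same generation do not define a zero spacing), upper =
# 10 * span.
length_scale_bounds <- function(t) {
  ts <- sort(unique(t))
  if (length(ts) < 2) abort("Need at least two distinct time points.")
  c(lower = min(diff(ts)), upper = 10 * (max(ts) - min(ts)))
}

#' Fit the time-dependent GP by maximising the marginal likelihood
#'
#' Optimises (length scale, signal variance, white-noise variance) of the
#' model `K_SE + sn2 I + diag(fbb)` in log space with analytic gradients
#' (L-BFGS-B), initialised at the best point of a scale-free grid: length
#' scale in span x {1/8, 1/4, 1/2, 1, 2}, signal and noise variances at
#' {0.1, 1, 10} x and {0.01, 0.1, 1} x the observed variance, all clipped to
#' bounds. The returned fit is the better of the best grid point and the
#' refined optimum, so a diverging refinement can never lose to its start.
#'
#' @param t Time vector (replicates as repeated rows at the same time).
#' @param y_centered Centered posterior means.
#' @param fbb Per-observation fixed variances.
#' @return A list of class `gp_fit`: `length_scale`, `signal_variance`,
#'   `noise_variance`, `log_ml`, `converged`, `n_grid`, `model = "dependent"`.
#' @export
gp_fit_dependent <- function(t, y_centered, fbb) {
  lb <- length_scale_bounds(t)
  span <- max(t) - min(t)
  D2 <- outer(t, t, "-")^2
  v <- mean(y_centered^2)
  if (v < 1e-12) v <- 1e-8
  grid <- expand.grid(
    l = pmin(pmax(span * c(1 / 8, 1 / 4, 1 / 2, 1, 2), lb["lower"]), lb["upper"]),
    sf2 = pmax(c(0.1, 1, 10) * v, SF2_FLOOR),
    sn2 = pmax(c(0.01, 0.1, 1) * v, SN2_FLOOR)
  )
  obj <- function(th) {
    val <- logml_and_grad(th, D2, y_centered, fbb)$value
    if (!is.finite(val)) 1e10 else -val
  }
  gr <- function(th) {
    g <- logml_and_grad(th, D2, y_centered, fbb)$grad
    if (any(!is.finite(g))) rep(0, 3) else -g
  }
  theta_grid <- log(as.matrix(grid))
  vals <- apply(theta_grid, 1, obj)
  if (all(vals >= 1e10)) {
    return(structure(list(length_scale = NA_real_, signal_variance = NA_real_,
                          noise_variance = NA_real_, log_ml = NA_real_,
                          converged = FALSE, n_grid = nrow(grid),
                          model = "dependent"), class = "gp_fit"))
  }
  best <- which.min(vals)
  lower <- log(c(lb[["lower"]], SF2_FLOOR, SN2_FLOOR))
  upper <- log(c(lb[["upper"]], 1e2, 1e2))
  start <- pmin(pmax(theta_grid[best, ], lower), upper)
  opt <- tryCatch(
    optim(start, obj, gr, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 200)),
    error = function(e) list(par = start, value = vals[best], convergence = 99L)
  )
  if (!is.finite(opt$value) || opt$value > vals[best]) {
    opt <- list(par = start, value = vals[best], convergence = 99L)
  }
  p <- exp(opt$par)
  structure(list(length_scale = p[1], signal_variance = p[2],
                 noise_variance = p[3], log_ml = -opt$value,
                 converged = identical(opt$convergence, 0L),
                 n_grid = nrow(grid), model = "dependent"),
            class = "gp_fit")
}

#' Fit the time-independent (constant + noise) model
#'
#' The time-independent model has diagonal covariance `sn2 I + diag(fbb)`;
#' the single free parameter `sn2` is found by a log-space grid scan followed
#' by golden-section refinement around the best grid point.
#'
#' @inheritParams gp_fit_dependent
#' @return A list of class `gp_fit` with `noise_variance`, `log_ml`,
#'   `converged`, `model = "independent"` (no kernel parameters).
#' @export
gp_fit_independent <- function(y_centered, fbb) {
  fbb <- rep_len(fbb, length(y_centered))
  loglik <- function(log_sn2) {
    sum(dnorm(y_centered, 0, sqrt(exp(log_sn2) + fbb), log = TRUE))
  }
  v <- max(mean(y_centered^2), 1e-8)
  lg <- seq(log(SN2_FLOOR), log(100 * v), length.out = 61)
  vals <- vapply(lg, loglik, numeric(1))
  i <- which.max(vals)
  bracket <- c(lg[max(1, i - 1)], lg[min(length(lg), i + 1)])
  ref <- optimize(loglik, interval = bracket, maximum = TRUE, tol = 1e-10)
  if (ref$objective >= vals[i]) {
    sn2 <- exp(ref$maximum); lm <- ref$objective
  } else {
    sn2 <- exp(lg[i]); lm <- vals[i]
  }
  structure(list(length_scale = NA_real_, signal_variance = NA_real_,
                 noise_variance = sn2, log_ml = lm, converged = TRUE,
                 n_grid = length(lg), model = "independent"),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit: %s model>\n", x$model))
  if (x$model == "dependent") {
    cat(sprintf("  length_scale = %.4g, signal_variance = %.4g\n",
                x$length_scale, x$signal_variance))
  }
  cat(sprintf("  noise_variance = %.4g, log_ml = %.6f\n",
              x$noise_variance, x$log_ml))
  invisible(x)
}
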