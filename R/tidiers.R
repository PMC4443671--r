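# broom-style tidiers for fitted objects.

#' Tidy a per-SNP BBGP fit
#'
#' One row per hyperparameter per model: the time-dependent model's length
#' scale, signal variance and noise variance, and the time-independent
#' model's noise variance.
#'
#' @param x A `bbgp_fit` object.
#' @param ... Unused.
#' @return A tibble with `model`, `term`, `estimate`.
#' @export
tidy.bbgp_fit <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(model = character(), term = character(),
                          estimate = numeric()))
  }
  tibble::tibble(
    model = c(rep("time-dependent", 3), "time-independent"),
    term = c("length_scale", "signal_variance", "noise_variance",
             "noise_variance"),
    estimate = c(x$fit_dep$length_scale, x$fit_dep$signal_variance,
                 x$fit_dep$noise_variance, x$fit_indep$noise_variance)
  )
}

#' One-row summary of a per-SNP BBGP fit
#'
#' @param x A `bbgp_fit` object.
#' @param ... Unused.
#' @return A tibble with `ln_bf`, `log_ml_dep`, `log_ml_indep`, `n_obs`,
#'   `n_timepoints`, `status`.
#' @export
glance.bbgp_fit <- function(x, ...) {
  tibble::tibble(
    ln_bf = x$ln_bf,
    log_ml_dep = if (is.null(x$fit_dep)) NA_real_ else x$fit_dep$log_ml,
    log_ml_indep = if (is.null(x$fit_indep)) NA_real_ else x$fit_indep$log_ml,
    n_obs = nrow(x$data),
    n_timepoints = length(unique(x$data$gen)),
    status = x$status
  )
}

#' Tidy a GP fit
#'
#' @param x A `gp_fit` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`.
#' @export
tidy.gp_fit <- function(x, ...) {
  terms <- if (x$model == "dependent") {
    c("length_scale", "signal_variance", "noise_variance")
  } else {
    "noise_variance"
  }
  est <- if (x$model == "dependent") {
    c(x$length_scale, x$signal_variance, x$noise_variance)
  } else {
    x$noise_variance
  }
  tibble::tibble(term = terms, estimate = est)
}

#' @rdname tidy.gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(log_ml = x$log_ml, converged = x$converged, model = x$model)
}
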