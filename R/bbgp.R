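# Per-SNP beta-binomial Gaussian process test: prepare the centered data,
# fit time-dependent and time-independent models, score by the log Bayes
# factor, and rank.

#' Prepare one SNP's observations for GP fitting
#'
#' Runs the beta-binomial posterior per observation and centers the posterior
#' means jointly across all replicates and time points: all replicates are
#' treated as repeated observations of one shared latent trajectory, so a
#' single mean is subtracted from the whole vector. The posterior variances
#' become the fixed (FBB) noise vector.
#'
#' @param data Observations for a single SNP: columns `gen`, `replicate`,
#'   `y`, `n`.
#' @param alpha,beta Beta prior parameters.
#' @return A list with `t`, `y_centered`, `fbb`, `center`, `ok` and (when not
#'   ok) `reason`. `ok` is `FALSE` with fewer than two distinct generations.
#' @export
prepare_snp <- function(data, alpha = 1, beta = 1) {
  stopifnot(all(c("gen", "y", "n") %in% names(data)))
  post <- freq_posterior(data, alpha = alpha, beta = beta)
  t <- as.numeric(post$gen)
  if (length(unique(t)) < 2) {
    return(list(t = t, ok = FALSE, reason = "fewer than 2 distinct time points"))
  }
  center <- mean(post$m)
  list(t = t, y_centered = post$m - center, fbb = post$s2, center = center,
       ok = TRUE)
}

#' Natural-log Bayes factor between two fitted models
#'
#' The maximised log marginal likelihood of the time-dependent model minus
#' that of the time-independent one. Because the time-independent model is
#' nested in the time-dependent one (signal variance -> 0), the value is
#' non-negative up to optimisation tolerance; large values indicate temporal
#' structure beyond sampling noise.
#'
#' @param fit_dep,fit_indep `gp_fit` objects from [gp_fit_dependent()] and
#'   [gp_fit_independent()].
#' @return The log Bayes factor (natural log).
#' @export
log_bayes_factor <- function(fit_dep, fit_indep) {
  if (!is.finite(fit_dep$log_ml) || !is.finite(fit_indep$log_ml)) {
    abort("Both fits must have finite log marginal likelihoods.")
  }
  fit_dep$log_ml - fit_indep$log_ml
}

#' Fit the BBGP model pair for a single SNP
#'
#' Fits the time-dependent and time-independent models on the centered
#' posterior means. The time-independent optimum, embedded at the
#' signal-variance floor, is always included as a candidate for the
#' time-dependent fit, so the nested-model bound `ln BF >= 0` holds up to
#' numerical tolerance by construction.
#'
#' @inheritParams prepare_snp
#' @return An object of class `bbgp_fit`: `prep`, `fit_dep`, `fit_indep`,
#'   `ln_bf`, `status` (`"ok"` or `"failed"`).
#' @examples
#' obs <- tidyr::expand_grid(gen = c(0, 14, 28, 44, 60), replicate = 1:3)
#' obs$n <- 45L
#' obs$y <- rbinom(nrow(obs), obs$n, plogis((obs$gen - 30) / 8))
#' fit <- bbgp_fit_snp(obs)
#' fit$ln_bf
#' @export
bbgp_fit_snp <- function(data, alpha = 1, beta = 1) {
  prep <- prepare_snp(data, alpha = alpha, beta = beta)
  out <- structure(list(prep = prep, data = tibble::as_tibble(data),
                        fit_dep = NULL, fit_indep = NULL,
                        ln_bf = NA_real_, status = "failed"),
                   class = "bbgp_fit")
  if (!isTRUE(prep$ok)) return(out)
  fit_indep <- gp_fit_independent(prep$y_centered, prep$fbb)
  fit_dep <- gp_fit_dependent(prep$t, prep$y_centered, prep$fbb)
  if (!is.finite(fit_indep$log_ml) || !is.finite(fit_dep$log_ml)) return(out)
  # nested candidate: the independent optimum expressed in the dependent
  # parameterisation (sf2 at its floor, any admissible length scale)
  lb <- length_scale_bounds(prep$t)
  C0 <- assemble_covariance(
    prep$t,
    kernel = list(length_scale = lb[["upper"]], signal_variance = SF2_FLOOR),
    noise_variance = max(fit_indep$noise_variance, SN2_FLOOR),
    fbb = prep$fbb
  )
  lm0 <- gp_log_marginal(prep$y_centered, C0)
  if (is.finite(lm0) && lm0 > fit_dep$log_ml) {
    fit_dep$length_scale <- lb[["upper"]]
    fit_dep$signal_variance <- SF2_FLOOR
    fit_dep$noise_variance <- max(fit_indep$noise_variance, SN2_FLOOR)
    fit_dep$log_ml <- lm0
  }
  out$fit_dep <- fit_dep
  out$fit_indep <- fit_indep
  out$ln_bf <- log_bayes_factor(fit_dep, fit_indep)
  out$status <- "ok"
  out
}

#' @export
print.bbgp_fit <- function(x, ...) {
  cat("<bbgp_fit>\n")
  if (x$status == "ok") {
    cat(sprintf("  ln BF = %.4f  (log ML: dependent %.4f, independent %.4f)\n",
                x$ln_bf, x$fit_dep$log_ml, x$fit_indep$log_ml))
  } else {
    cat("  status: failed -", x$prep$reason %||% "fit failure", "\n")
  }
  invisible(x)
}

#' Bayes-factor scan over all SNPs in a count table
#'
#' The main entry point of the package: for every SNP in a tidy table of
#' per-observation allele counts, computes beta-binomial posteriors, fits the
#' time-dependent and time-independent BBGP models, and returns one row per
#' SNP ranked by the log Bayes factor.
#'
#' @param data A data frame with one row per observation: SNP identifier
#'   columns (`chrom` + `pos`, or `snp_id`), `gen`, `replicate`, `y`, `n`.
#'   Extra constant-per-SNP columns (e.g. `allele1`, `allele2`) are carried
#'   through.
#' @param alpha,beta Beta prior parameters (default uniform).
#' @param log10 If `TRUE`, report `log10_bf` alongside `ln_bf` for display.
#' @return A tibble of class `bbgp_scan`, ranked by descending `ln_bf`, with
#'   columns `ln_bf`, `l_hat`, `sf2_hat`, `sn2_hat_dep`, `sn2_hat_indep`,
#'   `log_ml_dep`, `log_ml_indep`, `status`.
#' @seealso [cmh_test()] for the classical two-time-point comparator,
#'   [evaluate_ranking()] to score a scan against simulation truth.
#' @export
bbgp_test <- function(data, alpha = 1, beta = 1, log10 = FALSE) {
  id_cols <- snp_id_cols(data)
  carry <- setdiff(names(data), c(id_cols, "gen", "replicate", "y", "n", "m", "s2"))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(id_cols)))
  res <- dplyr::group_modify(grouped, function(df, key) {
    fit <- bbgp_fit_snp(df, alpha = alpha, beta = beta)
    row <- tibble::tibble(
      ln_bf = fit$ln_bf,
      l_hat = fit$fit_dep$length_scale %||% NA_real_,
      sf2_hat = fit$fit_dep$signal_variance %||% NA_real_,
      sn2_hat_dep = fit$fit_dep$noise_variance %||% NA_real_,
      sn2_hat_indep = fit$fit_indep$noise_variance %||% NA_real_,
      log_ml_dep = fit$fit_dep$log_ml %||% NA_real_,
      log_ml_indep = fit$fit_indep$log_ml %||% NA_real_,
      status = fit$status
    )
    for (col in carry) {
      u <- unique(df[[col]])
      if (length(u) == 1) row[[col]] <- u
    }
    row
  })
  res <- dplyr::ungroup(res)
  if (log10) res$log10_bf <- res$ln_bf / log(10)
  failed <- sum(res$status != "ok")
  if (failed > 0) {
    warn(sprintf("%d SNP(s) failed to fit and are ranked last.", failed))
  }
  res <- rank_snps(res)
  class(res) <- c("bbgp_scan", class(res))
  res
}

#' Order a Bayes-factor table for reporting
#'
#' Descending `ln_bf`; ties broken by ascending SNP identifier (`chrom`,
#' `pos` or `snp_id`) so the ranking is deterministic; failed fits sort last.
#'
#' @param records A tibble with at least `ln_bf` and `status`.
#' @return The reordered tibble with a `rank` column.
#' @export
rank_snps <- function(records) {
  if (nrow(records) == 0) return(records)
  id_cols <- snp_id_cols(records)
  ord <- dplyr::arrange(
    records,
    .data$status != "ok",
    dplyr::desc(.data$ln_bf),
    dplyr::across(dplyr::all_of(id_cols))
  )
  ord$rank <- seq_len(nrow(ord))
  ord
}
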