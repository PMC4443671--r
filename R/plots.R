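# ggplot2 figures for the main result types.

#' Plot a per-SNP BBGP fit
#'
#' Shows the beta-binomial posterior means with plus/minus 2 posterior
#' standard deviation error bars and, for the time-dependent model, the GP
#' posterior mean with a plus/minus 2 standard deviation band over a fine
#' time grid — the standard visual check that the fitted trajectory tracks
#' the observations.
#'
#' @param object A `bbgp_fit` object with `status == "ok"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bbgp_fit <- function(object, ...) {
  if (object$status != "ok") abort("Cannot plot a failed fit.")
  prep <- object$prep
  obs <- tibble::tibble(
    gen = prep$t, m = prep$y_centered + prep$center,
    sd = sqrt(prep$fbb),
    replicate = factor(object$data$replicate)
  )
  grid <- seq(min(prep$t), max(prep$t), length.out = 101)
  C <- assemble_covariance(
    prep$t,
    kernel = list(length_scale = object$fit_dep$length_scale,
                  signal_variance = object$fit_dep$signal_variance),
    noise_variance = object$fit_dep$noise_variance, fbb = prep$fbb
  )
  pred <- gp_predict(grid, prep$t, prep$y_centered,
                     kernel = list(length_scale = object$fit_dep$length_scale,
                                   signal_variance = object$fit_dep$signal_variance),
                     C = C)
  band <- tibble::tibble(
    gen = grid, mean = pred$mean + prep$center,
    sd = sqrt(pmax(diag(pred$cov), 0))
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$gen)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                      ymax = .data$mean + 2 * .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$mean),
                       colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - 2 * .data$sd,
                                        ymax = .data$m + 2 * .data$sd,
                                        colour = .data$replicate),
                           width = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$m, colour = .data$replicate)) +
    ggplot2::labs(x = "generation", y = "allele frequency (posterior mean)",
                  title = sprintf("ln BF = %.2f", object$ln_bf)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a Bayes-factor scan
#'
#' @param object A `bbgp_scan` tibble from [bbgp_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bbgp_scan <- function(object, ...) {
  id_cols <- snp_id_cols(object)
  x <- if ("pos" %in% id_cols) "pos" else id_cols[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data$ln_bf)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = x, y = "ln BF") +
    ggplot2::theme_minimal()
}

#' Trajectory plot of a simulated experiment
#'
#' Population allele-frequency trajectories per replicate, coloured by
#' truth label.
#'
#' @param object An `er_sim` object.
#' @param max_loci Plot at most this many loci per label (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.er_sim <- function(object, max_loci = 25, ...) {
  keep <- dplyr::slice_head(dplyr::group_by(object$truth, .data$label),
                            n = max_loci)
  df <- dplyr::inner_join(object$trajectories,
                          dplyr::select(keep, "chrom", "pos", "label"),
                          by = c("chrom", "pos"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gen, y = .data$freq,
                                   group = interaction(.data$pos, .data$replicate),
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "generation", y = "population allele frequency") +
    ggplot2::theme_minimal()
}

#' Precision-recall curve plot
#'
#' @param curve A tibble from [pr_curve()], or a named list of such tibbles
#'   to overlay several rankers.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(curve) {
  if (is.data.frame(curve)) curve <- list(ranking = curve)
  df <- dplyr::bind_rows(curve, .id = "ranker")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$ranker)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
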