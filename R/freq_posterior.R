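#' Conjugate beta-binomial posterior update for allele counts
#'
#' Observing `y` reads carrying the focal allele out of `n` total reads at a
#' site, with a Beta(alpha, beta) prior on the population allele frequency,
#' yields a Beta(alpha + y, beta + n - y) posterior. With the default uniform
#' Beta(1, 1) prior the posterior is symmetric under relabelling of the two
#' alleles (y -> n - y), which makes every downstream score invariant to the
#' choice of focal allele.
#'
#' @param y Integer vector of focal-allele read counts.
#' @param n Integer vector of total sequencing depths, `n >= y`.
#' @param alpha,beta Positive prior shape parameters; default uniform prior.
#' @param snp_id Optional identifier used in error messages.
#'
#' @return A tibble with columns `alpha_star` and `beta_star`.
#' @examples
#' beta_posterior_update(5, 10)          # Beta(6, 6)
#' beta_posterior_update(0, 0)           # no data: the prior, Beta(1, 1)
#' @export
beta_posterior_update <- function(y, n, alpha = 1, beta = 1, snp_id = NULL) {
  check_counts(y, n, snp_id)
  if (any(alpha <= 0) || any(beta <= 0)) {
    abort("Prior parameters `alpha` and `beta` must be positive.")
  }
  tibble::tibble(alpha_star = alpha + y, beta_star = beta + n - y)
}

check_counts <- function(y, n, snp_id = NULL) {
  bad <- which(!is.finite(y) | !is.finite(n) | y < 0 | n < 0 | y > n)
  if (length(bad)) {
    where <- if (is.null(snp_id)) "" else paste0(" at SNP ", snp_id[1])
    abort(sprintf(
      "Invalid counts%s, observation(s) %s: need 0 <= y <= n (got y = %s, n = %s).",
      where, paste(bad, collapse = ", "),
      paste(y[bad], collapse = ", "), paste(n[bad], collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Posterior mean and variance of an allele frequency
#'
#' Moments of a Beta(a, b) posterior: mean `a / (a + b)` and variance
#' `a b / ((a + b)^2 (a + b + 1))`. These are the quantities fed into the
#' Gaussian process stage: the mean as the observation, the variance as known
#' per-observation noise. Deeper sequencing shrinks the variance, so the GP
#' automatically down-weights shallowly covered observations.
#'
#' @param alpha_star,beta_star Positive posterior shape parameters.
#' @return A tibble with columns `m` (posterior mean, in `[0, 1]`) and `s2`
#'   (posterior variance, in `(0, 1/12]`).
#' @examples
#' beta_posterior_moments(6, 6)   # m = 0.5, s2 = 36 / (144 * 13)
#' @export
beta_posterior_moments <- function(alpha_star, beta_star) {
  if (any(alpha_star <= 0) || any(beta_star <= 0)) {
    abort("Posterior parameters must be positive.")
  }
  tot <- alpha_star + beta_star
  tibble::tibble(
    m = alpha_star / tot,
    s2 = alpha_star * beta_star / (tot^2 * (tot + 1))
  )
}

#' Add beta-binomial frequency posteriors to an allele-count table
#'
#' Takes a tidy table of per-observation counts and appends the posterior mean
#' `m` and variance `s2` of the allele frequency under a Beta(`alpha`,
#' `beta`)-binomial model. Zero-depth observations (`n = 0`) are kept by
#' default and get the prior moments (m = 0.5, s2 = 1/12 under the uniform
#' prior): the large variance makes them nearly uninformative downstream while
#' keeping one row per planned observation.
#'
#' @param data A data frame with integer columns `y` (focal-allele reads) and
#'   `n` (depth); any other columns are passed through.
#' @param alpha,beta Prior shape parameters (default uniform).
#' @param drop_zero_depth If `TRUE`, rows with `n == 0` are removed instead of
#'   receiving the prior moments.
#' @return The input tibble with columns `m` and `s2` appended.
#' @examples
#' obs <- tibble::tibble(gen = c(0, 60), replicate = 1, y = c(5, 45), n = c(10, 45))
#' freq_posterior(obs)
#' @export
freq_posterior <- function(data, alpha = 1, beta = 1, drop_zero_depth = FALSE) {
  stopifnot(is.data.frame(data), all(c("y", "n") %in% names(data)))
  id <- if (any(c("snp_id", "chrom") %in% names(data))) {
    do.call(paste, c(data[intersect(c("chrom", "pos", "snp_id"), names(data))], sep = ":"))
  }
  check_counts(data$y, data$n, id)
  if (drop_zero_depth) data <- dplyr::filter(data, .data$n > 0)
  post <- beta_posterior_update(data$y, data$n, alpha, beta)
  mom <- beta_posterior_moments(post$alpha_star, post$beta_star)
  dplyr::bind_cols(tibble::as_tibble(data), mom)
}
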