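# Cochran-Mantel-Haenszel test on replicate-stratified 2x2 allele-count
# tables between the base and end generations: the classical comparator for
# detecting consistent allele-frequency change across E&R replicates.

#' Build replicate-stratified 2x2 tables from one SNP's observations
#'
#' For each replicate, forms the 2x2 table of allele counts (rows: allele 1 /
#' allele 2; columns: base / end generation). Intermediate time points are
#' ignored — the CMH test only uses the first and last samples. Replicates
#' missing either time point, or with zero depth at one of them, are dropped
#' with a warning.
#'
#' @param data One SNP's observations: columns `gen`, `replicate`, `y`, `n`.
#' @param base_gen,end_gen Generations to compare.
#' @return A list of 2x2 matrices, one per retained replicate; empty if all
#'   replicates were dropped.
#' @export
counts_to_tables <- function(data, base_gen, end_gen) {
  stopifnot(all(c("gen", "replicate", "y", "n") %in% names(data)))
  tables <- list()
  dropped <- character()
  for (r in unique(data$replicate)) {
    b <- data[data$replicate == r & data$gen == base_gen, ]
    e <- data[data$replicate == r & data$gen == end_gen, ]
    if (nrow(b) != 1 || nrow(e) != 1 || b$n == 0 || e$n == 0) {
      dropped <- c(dropped, as.character(r))
      next
    }
    tables[[length(tables) + 1L]] <- matrix(
      c(b$y, b$n - b$y, e$y, e$n - e$y), nrow = 2,
      dimnames = list(allele = c("a1", "a2"), gen = c("base", "end"))
    )
  }
  if (length(dropped)) {
    warn(sprintf("Dropped replicate(s) %s: missing or zero-depth base/end sample.",
                 paste(dropped, collapse = ", ")))
  }
  tables
}

#' Cochran-Mantel-Haenszel statistic for stratified 2x2 tables
#'
#' `chi2 = (|sum_r (a_r - E[a_r])| - cc)^2 / sum_r Var(a_r)` with `a_r` the
#' top-left cell of stratum r, `E[a_r] = row1 * col1 / N`, `Var(a_r) =
#' row1 * row2 * col1 * col2 / (N^2 (N - 1))`, and `cc = 0.5` when the
#' continuity correction is on (default off, giving a smooth ranking
#' statistic). The statistic is chi-squared with 1 degree of freedom under
#' the common-odds-ratio-of-one null.
#'
#' @param tables List of 2x2 matrices as from [counts_to_tables()].
#' @param continuity_correction Apply the 0.5 continuity correction?
#' @return A list with `chi2`, `p`, `df = 1`, `n_strata`. Degenerate input
#'   (all strata with a zero margin) gives `NA` statistic.
#' @examples
#' tab <- matrix(c(20, 5, 5, 20), 2)
#' cmh_statistic(list(tab))$chi2   # about 17.64
#' @export
cmh_statistic <- function(tables, continuity_correction = FALSE) {
  if (length(tables) == 0) {
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L, n_strata = 0L))
  }
  num <- 0; denom <- 0; used <- 0L
  for (tab in tables) {
    if (any(tab < 0)) abort("Table cells must be non-negative.")
    N <- sum(tab)
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    if (N <= 1 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next # degenerate
    num <- num + tab[1, 1] - r1 * c1 / N
    denom <- denom + r1 * r2 * c1 * c2 / (N^2 * (N - 1))
    used <- used + 1L
  }
  if (used == 0L || denom == 0) {
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L, n_strata = 0L))
  }
  cc <- if (continuity_correction) 0.5 else 0
  chi2 <- (max(abs(num) - cc, 0))^2 / denom
  p <- max(pchisq(chi2, df = 1, lower.tail = FALSE), .Machine$double.xmin)
  list(chi2 = chi2, p = p, df = 1L, n_strata = used)
}

#' CMH scan over all SNPs in a count table
#'
#' Runs the replicate-stratified CMH test per SNP between two generations and
#' returns one row per SNP ranked by ascending p-value. Underflowing p-values
#' are clamped to the smallest positive double rather than reported as zero.
#'
#' @param data Tidy per-observation count table as in [bbgp_test()].
#' @param base_gen,end_gen Generations to compare; default the smallest and
#'   largest generation present.
#' @param continuity_correction Apply the 0.5 continuity correction
#'   (default off).
#' @return A tibble of class `cmh_scan` with `chi2`, `p`, `n_strata`,
#'   `status`, ranked by [rank_by_cmh()].
#' @export
cmh_test <- function(data, base_gen = NULL, end_gen = NULL,
                     continuity_correction = FALSE) {
  id_cols <- snp_id_cols(data)
  base_gen <- base_gen %||% min(data$gen)
  end_gen <- end_gen %||% max(data$gen)
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(id_cols)))
  res <- dplyr::group_modify(grouped, function(df, key) {
    tabs <- counts_to_tables(df, base_gen, end_gen)
    st <- cmh_statistic(tabs, continuity_correction)
    tibble::tibble(chi2 = st$chi2, p = st$p, n_strata = st$n_strata,
                   status = if (is.na(st$chi2)) "failed" else "ok")
  })
  res <- rank_by_cmh(dplyr::ungroup(res))
  class(res) <- c("cmh_scan", class(res))
  res
}

#' Order a CMH result table for reporting
#'
#' Ascending p-value; ties broken by descending statistic, then ascending SNP
#' identifier; failed tests last.
#'
#' @param records A tibble with `p`, `chi2`, `status`.
#' @return The reordered tibble with a `rank` column.
#' @export
rank_by_cmh <- function(records) {
  if (nrow(records) == 0) return(records)
  id_cols <- snp_id_cols(records)
  ord <- dplyr::arrange(
    records,
    .data$status != "ok",
    .data$p,
    dplyr::desc(.data$chi2),
    dplyr::across(dplyr::all_of(id_cols))
  )
  ord$rank <- seq_len(nrow(ord))
  ord
}
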