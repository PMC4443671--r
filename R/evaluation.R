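# Ranking evaluation: precision, recall, precision-recall curves, and
# average precision, the headline metric for comparing rankers that return
# the full SNP list ordered by evidence of selection.

#' Precision and recall at a cutoff
#'
#' `precision(k) = TP(k) / k`, `recall(k) = TP(k) / n_positives`, where
#' `TP(k)` is the number of true positives among the top `k` ranked items.
#'
#' @param ranked_ids Vector of item identifiers, best first, no duplicates.
#' @param positives Vector of identifiers of the true positives.
#' @param k Cutoff, `1 <= k <= length(ranked_ids)`.
#' @return A tibble with columns `k`, `precision`, `recall`.
#' @export
precision_recall_at_k <- function(ranked_ids, positives, k) {
  check_ranking(ranked_ids, positives)
  stopifnot(k >= 1, k <= length(ranked_ids))
  tp <- sum(ranked_ids[seq_len(k)] %in% positives)
  tibble::tibble(k = k, precision = tp / k, recall = tp / length(positives))
}

#' Precision-recall curve of a ranking
#'
#' Precision and recall at every cutoff `k = 1..N`.
#'
#' @inheritParams precision_recall_at_k
#' @return A tibble with `k`, `precision`, `recall`, `is_positive`.
#' @export
pr_curve <- function(ranked_ids, positives) {
  check_ranking(ranked_ids, positives)
  hit <- ranked_ids %in% positives
  k <- seq_along(ranked_ids)
  tibble::tibble(k = k, precision = cumsum(hit) / k,
                 recall = cumsum(hit) / length(positives), is_positive = hit)
}

#' Average precision of a ranking
#'
#' The mean of `precision(k)` over the ranks `k` at which a true positive is
#' returned: `aveP = sum_k precision(k) * 1[item k positive] / n_positives`.
#' Equals 1 for a perfect ranking and approximately the positive fraction for
#' a random one.
#'
#' @inheritParams precision_recall_at_k
#' @return A number in `(0, 1]`.
#' @examples
#' average_precision(c("a", "b", "c", "d"), positives = c("a", "c"))  # 5/6
#' @export
average_precision <- function(ranked_ids, positives) {
  check_ranking(ranked_ids, positives)
  if (length(positives) == 0) abort("Average precision needs at least one positive.")
  hit <- ranked_ids %in% positives
  pre <- cumsum(hit) / seq_along(hit)
  sum(pre[hit]) / length(positives)
}

check_ranking <- function(ranked_ids, positives) {
  if (anyDuplicated(ranked_ids)) abort("`ranked_ids` must not contain duplicates.")
  if (!all(positives %in% ranked_ids)) {
    abort("All `positives` must appear among `ranked_ids`.")
  }
  invisible(TRUE)
}

#' Average precision of a random ranking (line of no discrimination)
#'
#' The expected average precision of an uninformative ranking is taken as the
#' positive fraction `n_pos / n_total`, the constant baseline drawn on
#' precision-recall plots.
#'
#' @param n_pos Number of true positives.
#' @param n_total Total number of ranked items.
#' @return `n_pos / n_total`.
#' @export
random_baseline_ap <- function(n_pos, n_total) {
  stopifnot(n_pos > 0, n_pos <= n_total)
  n_pos / n_total
}

#' Score a results table against simulation truth
#'
#' Joins a ranked results table (from [bbgp_test()] or [cmh_test()]) with a
#' truth table, orders by the chosen score, and reports average precision
#' together with the random baseline.
#'
#' @param results A per-SNP results tibble with identifier columns and a
#'   score column.
#' @param truth A truth tibble with the same identifier columns and a `label`
#'   column where `"selected"` marks the positives.
#' @param score_col Name of the score column (e.g. `"ln_bf"` or `"p"`).
#' @param higher_is_better `TRUE` for Bayes factors, `FALSE` for p-values.
#' @return A one-row tibble: `ap`, `n_pos`, `n_total`, `baseline_ap`.
#' @export
evaluate_ranking <- function(results, truth, score_col = "ln_bf",
                             higher_is_better = TRUE) {
  id_cols <- snp_id_cols(results)
  joined <- dplyr::inner_join(
    dplyr::select(results, dplyr::all_of(c(id_cols, score_col, "status"))),
    dplyr::select(truth, dplyr::all_of(c(id_cols, "label"))),
    by = id_cols
  )
  score <- joined[[score_col]]
  if (!higher_is_better) score <- -score
  joined$.score <- score
  ranked <- dplyr::arrange(joined, .data$status != "ok",
                           dplyr::desc(.data$.score),
                           dplyr::across(dplyr::all_of(id_cols)))
  ids <- do.call(paste, c(ranked[id_cols], sep = ":"))
  pos <- ids[ranked$label == "selected"]
  tibble::tibble(
    ap = average_precision(ids, pos),
    n_pos = length(pos), n_total = length(ids),
    baseline_ap = random_baseline_ap(length(pos), length(ids))
  )
}
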