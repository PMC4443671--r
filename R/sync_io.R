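# PoPoolation2 sync-format input, bi-allelification, and results I/O.
# A sync line is: chromosome, 1-based position, reference base, then one
# "A:T:C:G:N:del" colon-separated count column per sequenced sample.

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Parse a "gen:replicate" sample-map string
#'
#' The sample map assigns each sync count column a (generation, replicate)
#' pair, in column order, e.g. `"0:1,0:2,60:1,60:2"`.
#'
#' @param x A comma-separated string of `gen:replicate` pairs, or a data
#'   frame already holding `gen` and `replicate` columns (returned as-is
#'   with a `sample` index).
#' @return A tibble with columns `sample`, `gen`, `replicate`.
#' @export
parse_sample_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gen", "replicate") %in% names(x)))
    out <- tibble::as_tibble(x)
    if (!"sample" %in% names(out)) out$sample <- seq_len(nrow(out))
  } else {
    parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      abort("Sample map entries must look like 'generation:replicate'.")
    }
    out <- tibble::tibble(
      sample = seq_along(parts),
      gen = as.numeric(vapply(parts, `[`, "", 1)),
      replicate = vapply(parts, `[`, "", 2)
    )
  }
  if (anyDuplicated(out[c("gen", "replicate")])) {
    abort("Each (generation, replicate) pair may appear only once in the sample map.")
  }
  if (any(is.na(out$gen))) abort("Sample-map generations must be numeric.")
  out
}

#' Read a sync file into a tidy long count table
#'
#' Parses a (possibly gzipped) PoPoolation2 sync file and returns one row per
#' site x sample with the six base counts as columns. Malformed lines are
#' reported with their line numbers.
#'
#' @param path Path to the sync file (`.gz` handled transparently).
#' @param sample_map Optional sample map (string or data frame, see
#'   [parse_sample_map()]); when given, `gen` and `replicate` columns are
#'   attached and the number of entries must match the sync columns.
#' @return A tibble with `chrom`, `pos`, `ref`, `sample`, count columns
#'   `A`, `T`, `C`, `G`, `N`, `del`, and (with a map) `gen`, `replicate`.
#' @export
read_sync <- function(path, sample_map = NULL) {
  if (!file.exists(path)) abort(sprintf("Sync file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), sample = integer(),
                          A = integer(), T = integer(), C = integer(),
                          G = integer(), N = integer(), del = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    abort(sprintf("Sync parse error at line(s) %s: need at least 4 tab-separated fields.",
                  paste(head(which(nf < 4), 5), collapse = ", ")))
  }
  if (length(unique(nf)) != 1) {
    abort(sprintf("Inconsistent sync column count at line(s) %s.",
                  paste(head(which(nf != nf[1]), 5), collapse = ", ")))
  }
  S <- nf[1] - 3L
  mat <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (any(is.na(pos))) {
    abort(sprintf("Non-integer position at line(s) %s.",
                  paste(head(which(is.na(pos)), 5), collapse = ", ")))
  }
  samples <- as.vector(t(mat[, -(1:3), drop = FALSE]))   # row-major: site-major order
  cnt <- strsplit(samples, ":", fixed = TRUE)
  if (any(lengths(cnt) != 6)) {
    bad_line <- unique(ceiling(which(lengths(cnt) != 6) / S))
    abort(sprintf("Sync parse error at line(s) %s: sample fields must be A:T:C:G:N:del sextuples.",
                  paste(head(bad_line, 5), collapse = ", ")))
  }
  cm <- matrix(suppressWarnings(as.integer(unlist(cnt))), ncol = 6, byrow = TRUE)
  if (any(is.na(cm)) || any(cm < 0)) {
    bad_line <- unique(ceiling(which(rowSums(is.na(cm) | cm < 0) > 0) / S))
    abort(sprintf("Non-integer or negative count at line(s) %s.",
                  paste(head(bad_line, 5), collapse = ", ")))
  }
  colnames(cm) <- SYNC_BASES
  out <- tibble::tibble(
    chrom = rep(mat[, 1], each = S),
    pos = rep(pos, each = S),
    ref = rep(mat[, 3], each = S),
    sample = rep(seq_len(S), times = length(lines))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(cm))
  if (!is.null(sample_map)) {
    map <- parse_sample_map(sample_map)
    if (nrow(map) != S) {
      abort(sprintf("Sample map has %d entries but the sync file has %d sample columns.",
                    nrow(map), S))
    }
    out <- dplyr::left_join(out, map, by = "sample")
  }
  out
}

#' Reduce sync records to bi-allelic rising-allele count series
#'
#' For each site, the two alleles with the highest total count over all
#' samples (among A, T, C, G; N and deletions are never counted) become the
#' allele pair; ties are broken in fixed base order A < C < G < T. Residual
#' third/fourth-allele counts are dropped from the depth under
#' `policy = "drop"` (the default — rare multi-allelic residues are most
#' often sequencing errors) or added to the minor allele under
#' `policy = "collapse"`. The reported count `y` is for the rising allele,
#' the one whose mean frequency increases from the first to the last sampled
#' generation; with the symmetric uniform prior the downstream tests do not
#' depend on this choice. Sites where fewer than two alleles are ever
#' observed are skipped as monomorphic.
#'
#' @param sync A long sync tibble from [read_sync()], with `gen` and
#'   `replicate` attached.
#' @param policy `"drop"` or `"collapse"`.
#' @return A tidy series tibble: `chrom`, `pos`, `allele1` (rising),
#'   `allele2`, `gen`, `replicate`, `y`, `n`.
#' @export
sync_to_series <- function(sync, policy = c("drop", "collapse")) {
  policy <- arg_match(policy)
  stopifnot(all(c("gen", "replicate") %in% names(sync)))
  bases <- c("A", "C", "G", "T")  # fixed tie-break order
  per_site <- dplyr::group_by(sync, .data$chrom, .data$pos)
  res <- dplyr::group_modify(per_site, function(df, key) {
    totals <- vapply(bases, function(b) sum(df[[b]]), numeric(1))
    observed <- sum(totals > 0)
    if (observed < 2) return(tibble::tibble())  # monomorphic, skipped
    ord <- order(-totals, seq_along(bases))     # count desc, then A<C<G<T
    a1 <- bases[ord[1]]; a2 <- bases[ord[2]]
    y1 <- df[[a1]]; y2 <- df[[a2]]
    rest <- rowSums(as.matrix(df[setdiff(bases, c(a1, a2))]))
    if (policy == "collapse") y2 <- y2 + rest
    n <- y1 + y2
    # rising allele: frequency increase from first to last sampled generation
    f <- function(cnt, gen_sel) {
      idx <- df$gen == gen_sel & n > 0
      if (!any(idx)) return(NA_real_)
      mean(cnt[idx] / n[idx])
    }
    g0 <- min(df$gen); g1 <- max(df$gen)
    rising_first <- !isTRUE(f(y1, g1) < f(y1, g0))
    if (!rising_first) {
      tmp <- a1; a1 <- a2; a2 <- tmp
      tmp <- y1; y1 <- y2; y2 <- tmp
    }
    tibble::tibble(allele1 = a1, allele2 = a2, gen = df$gen,
                   replicate = df$replicate, y = y1, n = n)
  })
  out <- dplyr::ungroup(res)
  skipped <- dplyr::n_distinct(sync[c("chrom", "pos")]) -
    dplyr::n_distinct(out[c("chrom", "pos")])
  if (skipped > 0) {
    inform(sprintf("Skipped %d monomorphic site(s).", skipped))
  }
  out
}

#' Write a per-SNP results table to TSV
#'
#' Deterministic column order, full double precision (round-trips through
#' [read_results()]).
#'
#' @param records A results tibble ([bbgp_test()] or [cmh_test()] output).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
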