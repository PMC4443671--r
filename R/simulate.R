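# Desk-scale evolve-and-resequence simulator: replicated Wright-Fisher
# evolution of unlinked bi-allelic loci with selection and dominance, plus
# Poisson-depth pool sequencing. Emulates the population dynamics of a
# moderate-size diploid E&R experiment (census ~1000, tens of generations);
# it does not model linkage, so hitchhiking of neutral flanking sites is
# absent by design.

#' Configuration for an evolve-and-resequence simulation
#'
#' Defaults reproduce the basic experimental setup of a moderate-size diploid
#' E&R study: census size 1000, 200 founder haplotypes, 5 replicates, 60
#' generations sampled at five roughly even generations, semi-dominant
#' selection `s = 0.1` on the selected loci, mean pool-sequencing depth 45,
#' and selected starting frequencies in `[0.12, 0.8]` so the favoured allele
#' is unlikely to be lost to drift early on.
#'
#' @param N Diploid census size per replicate.
#' @param H Number of founder haplotypes the base populations are drawn from.
#' @param R Number of replicate populations.
#' @param G Total number of generations.
#' @param sample_gens Generations at which populations are sequenced; must
#'   include 0 and `G`.
#' @param s Selection coefficient of the favoured allele at selected loci.
#' @param h Dominance coefficient (`0.5` = semi-dominance / additivity).
#' @param lambda_depth Mean of the Poisson per-site sequencing depth.
#' @param L_neutral,L_selected Numbers of neutral and selected loci.
#' @param p0_range_selected Starting-frequency interval for selected loci.
#' @param p0_range_neutral Starting-frequency interval for neutral loci (a
#'   uniform stand-in for an empirical founder frequency spectrum).
#' @param pool_size If non-`NULL`, the number of diploid individuals pooled
#'   for sequencing; reads are then drawn from a without-replacement pool
#'   sample of `2 * pool_size` chromosomes instead of the population
#'   frequency directly. Default `NULL` (sequence the population frequency).
#' @param seed Integer seed making the whole simulation reproducible.
#' @return A list of class `er_sim_config`.
#' @export
er_sim_config <- function(N = 1000, H = 200, R = 5, G = 60,
                          sample_gens = c(0, 14, 28, 44, 60),
                          s = 0.1, h = 0.5, lambda_depth = 45,
                          L_neutral = 500, L_selected = 25,
                          p0_range_selected = c(0.12, 0.8),
                          p0_range_neutral = c(0.05, 0.95),
                          pool_size = NULL, seed = 1L) {
  stopifnot(N > 0, H > 0, R > 0, G > 0, lambda_depth > 0,
            all(sample_gens >= 0), all(sample_gens <= G),
            0 %in% sample_gens, G %in% sample_gens,
            p0_range_selected[1] > 0, p0_range_selected[2] < 1)
  structure(
    list(N = N, H = H, R = R, G = G, sample_gens = sort(unique(sample_gens)),
         s = s, h = h, lambda_depth = lambda_depth,
         L_neutral = L_neutral, L_selected = L_selected,
         p0_range_selected = p0_range_selected,
         p0_range_neutral = p0_range_neutral,
         pool_size = pool_size, seed = as.integer(seed)),
    class = "er_sim_config"
  )
}

#' Found a replicate population from a finite haplotype pool
#'
#' The founder pool carries `round(H * p0)` copies of the focal allele among
#' `H` haplotypes; a replicate of `N` diploids is founded by drawing `2N`
#' haplotypes with replacement from that pool. Two-stage sampling, so founded
#' frequencies vary around `p0` more than a single binomial draw would.
#'
#' @param H Number of founder haplotypes.
#' @param N Diploid census size.
#' @param p0 Founder-pool allele frequency in `[0, 1]`.
#' @return Integer count of focal-allele copies among the `2N` founding
#'   chromosomes.
#' @export
found_replicate <- function(H, N, p0) {
  stopifnot(p0 >= 0, p0 <= 1)
  k <- round(H * p0)
  rbinom(1L, 2L * N, k / H)
}

#' Deterministic one-generation selection update
#'
#' Expected next-generation frequency under viability selection with genotype
#' fitnesses `1 + s` (AA), `1 + h s` (Aa) and `1` (aa), assuming
#' Hardy-Weinberg genotype proportions:
#' `p' = (p^2 (1+s) + p q (1+hs)) / wbar`, `q = 1 - p`.
#'
#' @param p Current allele frequency (vectorised).
#' @param s Selection coefficient.
#' @param h Dominance coefficient.
#' @return The post-selection expected frequency.
#' @examples
#' selection_update(0.5, 0.1, 0.5)  # 0.5375 / 1.05
#' @export
selection_update <- function(p, s, h) {
  q <- 1 - p
  wbar <- p^2 * (1 + s) + 2 * p * q * (1 + h * s) + q^2
  (p^2 * (1 + s) + p * q * (1 + h * s)) / wbar
}

#' One Wright-Fisher generation with selection
#'
#' Applies the deterministic selection update to the current frequency and
#' then draws the next generation as `Binomial(2N, p')` (random union of
#' gametes). Frequencies 0 and 1 are absorbing. Vectorised over loci.
#'
#' @param copy_count Integer vector of current allele-copy counts in `0..2N`.
#' @param N Diploid census size.
#' @param s,h Selection and dominance coefficients (vectorised over loci).
#' @return Integer vector of next-generation copy counts.
#' @export
wf_step <- function(copy_count, N, s, h) {
  stopifnot(all(copy_count >= 0), all(copy_count <= 2 * N))
  p <- copy_count / (2 * N)
  p_sel <- ifelse(p %in% c(0, 1), p, selection_update(p, s, h))
  rbinom(length(copy_count), 2L * N, p_sel)
}

#' Pool-sequence a site
#'
#' Sequencing depth is `Poisson(lambda_depth)` and the focal-allele read
#' count is `Binomial(n, freq)`. A depth of zero is a legal outcome.
#'
#' @param freq Population (or pool) allele frequencies in `[0, 1]`.
#' @param lambda_depth Mean depth.
#' @return A tibble with columns `y` and `n`.
#' @export
sequence_sample <- function(freq, lambda_depth) {
  stopifnot(all(freq >= 0), all(freq <= 1), lambda_depth > 0)
  n <- rpois(length(freq), lambda_depth)
  tibble::tibble(y = rbinom(length(freq), n, freq), n = n)
}

#' Simulate a replicated evolve-and-resequence experiment
#'
#' Evolves `L_selected + L_neutral` unlinked loci independently in `R`
#' replicate Wright-Fisher populations for `G` generations, recording the
#' population allele frequency at each sampled generation and pool-sequencing
#' it at Poisson depth. Selected loci start at a frequency drawn uniformly
#' from `p0_range_selected` (redrawn if founder-pool rounding would fix or
#' lose the allele) and evolve under `(s, h)`; neutral loci start uniformly in
#' `p0_range_neutral` and evolve with `s = 0`.
#'
#' @param config An [er_sim_config()] object.
#' @return A list of class `er_sim` with tibbles `truth` (chrom, pos, label,
#'   p0, s, h), `trajectories` (locus x replicate x sampled generation
#'   population frequencies) and `counts` (sequenced `y`, `n` per
#'   observation), plus the `config`.
#' @examples
#' sim <- simulate_experiment(er_sim_config(L_neutral = 10, L_selected = 2, seed = 7))
#' dplyr::count(sim$truth, label)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "er_sim_config"))
  set.seed(config$seed)
  L <- config$L_selected + config$L_neutral
  label <- rep(c("selected", "neutral"), c(config$L_selected, config$L_neutral))
  s_vec <- ifelse(label == "selected", config$s, 0)
  h_vec <- rep(config$h, L)

  p0 <- numeric(L)
  sel <- label == "selected"
  p0[sel] <- draw_selected_p0(sum(sel), config)
  p0[!sel] <- runif(sum(!sel), config$p0_range_neutral[1], config$p0_range_neutral[2])

  twoN <- 2L * config$N
  gens <- config$sample_gens
  freq <- array(NA_real_, dim = c(L, config$R, length(gens)),
                dimnames = list(NULL, NULL, paste0("g", gens)))
  for (r in seq_len(config$R)) {
    k <- round(config$H * p0)
    count <- rbinom(L, twoN, k / config$H)
    gi <- 1L
    for (g in 0:config$G) {
      if (g > 0) count <- wf_step(count, config$N, s_vec, h_vec)
      if (g == gens[gi]) {
        freq[, r, gi] <- count / twoN
        if (gi < length(gens)) gi <- gi + 1L
      }
    }
  }

  truth <- tibble::tibble(chrom = "sim", pos = seq_len(L), label = label,
                          p0 = p0, s = s_vec, h = h_vec)
  obs <- tidyr::expand_grid(pos = seq_len(L), replicate = seq_len(config$R),
                            gen = gens)
  obs$freq <- freq[cbind(obs$pos, obs$replicate, match(obs$gen, gens))]
  seq_freq <- obs$freq
  if (!is.null(config$pool_size)) {
    chrom_pool <- 2L * config$pool_size
    pooled <- rhyper(nrow(obs), m = round(obs$freq * twoN),
                     n = twoN - round(obs$freq * twoN), k = chrom_pool)
    seq_freq <- pooled / chrom_pool
  }
  reads <- sequence_sample(seq_freq, config$lambda_depth)
  counts <- dplyr::bind_cols(
    tibble::tibble(chrom = "sim", pos = obs$pos, gen = obs$gen,
                   replicate = obs$replicate),
    reads
  )
  trajectories <- tibble::tibble(chrom = "sim", pos = obs$pos, gen = obs$gen,
                                 replicate = obs$replicate, freq = obs$freq)
  structure(list(truth = truth, trajectories = trajectories, counts = counts,
                 config = config), class = "er_sim")
}

# redraw p0 until founder-pool rounding keeps the allele polymorphic
draw_selected_p0 <- function(n, config) {
  lo <- config$p0_range_selected[1]; hi <- config$p0_range_selected[2]
  p0 <- runif(n, lo, hi)
  for (i in seq_len(100)) {
    k <- round(config$H * p0)
    bad <- k <= 0 | k >= config$H
    if (!any(bad)) break
    inform(sprintf("Redrawing %d selected starting frequencies fixed/lost by founder rounding.",
                   sum(bad)))
    p0[bad] <- runif(sum(bad), lo, hi)
  }
  p0
}

#' @export
print.er_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<er_sim: %d loci (%d selected), %d replicates, %d generations>\n",
              nrow(x$truth), cfg$L_selected, cfg$R, cfg$G))
  cat(sprintf("  sampled at generations %s; mean depth %g\n",
              paste(cfg$sample_gens, collapse = ", "), cfg$lambda_depth))
  invisible(x)
}

#' Write a simulated experiment to sync, truth and config files
#'
#' Emits `<prefix>.sync` (PoPoolation2 sync format, focal allele as A, the
#' other allele as T; columns ordered by generation then replicate),
#' `<prefix>.truth.tsv` and `<prefix>.config.yaml`.
#'
#' @param sim An `er_sim` object.
#' @param prefix Output path prefix.
#' @return Invisibly, a list with the three paths and the `sample_map` string
#'   ("gen:replicate" per sync column).
#' @export
write_er_sim <- function(sim, prefix) {
  stopifnot(inherits(sim, "er_sim"))
  cfg <- sim$config
  cols <- tidyr::expand_grid(gen = cfg$sample_gens, replicate = seq_len(cfg$R))
  counts <- dplyr::arrange(sim$counts, .data$pos, match(
    paste(.data$gen, .data$replicate),
    paste(cols$gen, cols$replicate)
  ))
  sext <- sprintf("%d:%d:0:0:0:0", counts$y, counts$n - counts$y)
  mat <- matrix(sext, nrow = nrow(sim$truth), byrow = TRUE)
  lines <- paste(sim$truth$chrom, sim$truth$pos, "A",
                 apply(mat, 1, paste, collapse = "\t"), sep = "\t")
  sync_path <- paste0(prefix, ".sync")
  writeLines(lines, sync_path)
  truth_path <- paste0(prefix, ".truth.tsv")
  readr::write_tsv(sim$truth, truth_path)
  config_path <- paste0(prefix, ".config.yaml")
  yaml::write_yaml(unclass(cfg), config_path)
  invisible(list(sync = sync_path, truth = truth_path, config = config_path,
                 sample_map = paste(cols$gen, cols$replicate, sep = ":",
                                    collapse = ",")))
}
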