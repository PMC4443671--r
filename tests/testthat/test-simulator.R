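test_that("founding is two-stage sampling from the haplotype pool", {
  set.seed(501)
  expect_equal(found_replicate(200, 1000, 0), 0)
  expect_equal(found_replicate(200, 1000, 1), 2000)
  counts <- replicate(1e4, found_replicate(200, 1000, 0.5))
  expect_lt(abs(mean(counts) - 1000), 3 * sd(counts) / sqrt(1e4))
  # two-stage oracle: founder rounding is exact at p0 = 0.5, so the variance
  # is that of Binomial(2N, 100/200)
  expect_lt(abs(var(counts) - 2000 * 0.25), 4 * var(counts) / sqrt(5e3))
})

test_that("deterministic selection update follows the fitness recursion", {
  expect_equal(selection_update(0.5, 0.1, 0.5), 0.5375 / 1.05)
  expect_equal(selection_update(0.5, 0.1, 0.5), 0.511905, tolerance = 1e-6)
  expect_equal(selection_update(0.3, 0, 0.5), 0.3)   # neutral: identity
  # recessive favoured allele is shielded at low frequency:
  # the selection differential is O(p^2)
  p <- 1e-3
  expect_lt(selection_update(p, 0.1, 0) - p, 0.1 * p^2 * 2)
  expect_gt(selection_update(p, 0.1, 0), p)
})

test_that("the neutral Wright-Fisher step is a martingale", {
  set.seed(502)
  nxt <- wf_step(rep(800L, 2e4), N = 1000, s = 0, h = 0.5)
  expect_lt(abs(mean(nxt) - 800), 3 * sd(nxt) / sqrt(2e4))
  # absorbing boundaries
  expect_equal(wf_step(c(0L, 2000L), 1000, 0.1, 0.5), c(0, 2000))
})

test_that("neutral trajectories conserve the mean and match drift variance", {
  set.seed(503)
  cfg <- er_sim_config(L_neutral = 2000, L_selected = 0, R = 1, seed = 504)
  sim <- simulate_experiment(cfg)
  terminal <- dplyr::filter(sim$trajectories, .data$gen == 60)
  joined <- dplyr::inner_join(terminal, sim$truth, by = c("chrom", "pos"))
  dev <- joined$freq - joined$p0
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(nrow(joined)))
  # classical drift variance after G generations, plus founding noise
  G <- 60; N <- 1000; H <- 200
  p0 <- joined$p0
  k <- round(H * p0) / H
  drift_var <- k * (1 - k) * (1 - (1 - 1 / (2 * N))^G) +
    k * (1 - k) / (2 * N) * (1 - 1 / (2 * N))^G + (k - p0)^2
  resid <- dev^2 - drift_var
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
})

test_that("strong semi-dominant selection tracks the deterministic recursion", {
  # recursion oracle: 60 rounds of the selection update from p0 = 0.2
  p_det <- 0.2
  for (g in 1:60) p_det <- selection_update(p_det, 0.1, 0.5)
  expect_equal(p_det, 0.8131864, tolerance = 1e-6)
  set.seed(505)
  count <- rep(round(2000 * 0.2), 300)
  for (g in 1:60) count <- wf_step(count, 1000, 0.1, 0.5)
  freq <- count / 2000
  # the stochastic mean sits near (slightly below, by drift-induced loss of
  # high-fitness trajectories' concavity) the deterministic endpoint
  expect_lt(abs(mean(freq) - p_det), 0.05)
  expect_gt(mean(freq), 0.75)
})

test_that("neutral fixation probability approximates the starting frequency", {
  set.seed(506)
  N <- 50; p0 <- 0.3
  fixed <- replicate(400, {
    cc <- round(2 * N * p0)
    for (g in 1:2000) {
      if (cc %in% c(0, 2 * N)) break
      cc <- wf_step(cc, N, 0, 0.5)
    }
    cc == 2 * N
  })
  se <- sqrt(p0 * (1 - p0) / 400)
  expect_lt(abs(mean(fixed) - p0), 4 * se)
})

test_that("pool sequencing draws Poisson depth and binomial reads", {
  set.seed(507)
  expect_true(all(sequence_sample(rep(0, 100), 45)$y == 0))
  r1 <- sequence_sample(rep(1, 100), 45)
  expect_equal(r1$y, r1$n)
  r <- sequence_sample(rep(0.5, 1e5), 45)
  expect_lt(abs(mean(r$n) - 45), 3 * sd(r$n) / sqrt(1e5))
  expect_true(all(r$y <= r$n))
})

test_that("a simulation is reproducible and exchangeable across replicates", {
  cfg <- er_sim_config(L_neutral = 20, L_selected = 5, seed = 508)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$trajectories, s2$trajectories)
  # per-replicate terminal-frequency distributions are alike (exchangeability)
  set.seed(509)
  big <- simulate_experiment(er_sim_config(L_neutral = 400, L_selected = 0,
                                           R = 2, seed = 510))
  term <- dplyr::filter(big$trajectories, .data$gen == 60)
  ks <- suppressWarnings(stats::ks.test(term$freq[term$replicate == 1],
                                        term$freq[term$replicate == 2]))
  expect_gt(ks$p.value, 0.001)
})

test_that("truth labels, frequency bounds and generation-0 founding hold", {
  sim <- simulate_experiment(er_sim_config(L_neutral = 30, L_selected = 10,
                                           seed = 511))
  expect_equal(sum(sim$truth$label == "selected"), 10)
  expect_true(all(sim$truth$s[sim$truth$label == "neutral"] == 0))
  expect_true(all(sim$trajectories$freq >= 0 & sim$trajectories$freq <= 1))
  expect_true(all(sim$counts$y <= sim$counts$n))
  sel <- sim$truth$p0[sim$truth$label == "selected"]
  expect_true(all(sel >= 0.12 & sel <= 0.8))
})

test_that("the optional pool stage adds hypergeometric sampling noise", {
  cfg <- er_sim_config(L_neutral = 200, L_selected = 0, R = 1,
                       pool_size = 50, seed = 512)
  sim <- simulate_experiment(cfg)
  base <- dplyr::filter(sim$counts, .data$gen == 0)
  traj <- dplyr::filter(sim$trajectories, .data$gen == 0)
  # read frequencies still track population frequencies on average
  expect_lt(abs(mean(base$y / base$n) - mean(traj$freq)), 0.03)
})
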