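score_single <- function(stream) {
  b <- data.frame(i_start = 1L, i_stop = nrow(stream),
                  start_us = stream$timestamp_us[1],
                  stop_us = stream$timestamp_us[nrow(stream)],
                  duration_s = diff(range(stream$timestamp_us)) * 1e-6,
                  n_photons = nrow(stream),
                  DD = sum(stream$class == "DD"), AD = sum(stream$class == "AD"),
                  AA = sum(stream$class == "AA"), DA = sum(stream$class == "DA"))
  two_cde_scores(b, stream)
}

test_that("2CDE scores match the brute-force kernel oracle", {
  set.seed(21)
  for (i in 1:20) {
    s <- make_static_burst_stream(n_periods = sample(30:80, 1),
                                  per_gate = sample(2:4, 1),
                                  E = runif(1, 0.2, 0.8))
    got <- score_single(s)
    want <- brute_two_cde(s$timestamp_us, s$class, tau = 100)
    expect_equal(got$alex_2cde, unname(want["alex"]), tolerance = 1e-9)
    expect_equal(got$fret_2cde, unname(want["fret"]), tolerance = 1e-9)
  }
})

test_that("a static dual-labelled burst scores low on ALEX-2CDE, donor-only high", {
  set.seed(22)
  dual <- make_static_burst_stream(n_periods = 60, per_gate = 3, E = 0.4)
  expect_lt(score_single(dual)$alex_2cde, 12)
  expect_gt(score_single(dual)$fret_2cde, 0)

  # donor-only: all molecule photons in donor gates, only one stray Aex photon
  ts <- c(sort(sample(0:49, 30)) , 100 + sort(sample(0:49, 30)),
          200 + sort(sample(0:49, 30)), 375)
  ch <- c(rep("donor", 90), "acceptor")
  donly <- make_stream(sort(ts), ch)
  expect_gt(score_single(donly)$alex_2cde, 12)
})

test_that("a mid-burst acceptor bleach pushes FRET-2CDE outside the static band", {
  set.seed(23)
  # first half: high FRET (E = 0.8); second half: acceptor dark (E = 0)
  first <- make_static_burst_stream(n_periods = 40, per_gate = 3, E = 0.85)
  second <- make_static_burst_stream(n_periods = 40, per_gate = 3, E = 0.02)
  second$timestamp_us <- second$timestamp_us + 4000
  s <- make_stream(c(first$timestamp_us, second$timestamp_us),
                   c(first$channel, second$channel))
  sc <- score_single(s)
  want <- brute_two_cde(s$timestamp_us, s$class, tau = 100)
  expect_equal(sc$fret_2cde, unname(want["fret"]), tolerance = 1e-9)
  expect_true(sc$fret_2cde < 8 || sc$fret_2cde > 12)
})

test_that("filtering removes donor-only contaminants without losing dual bursts", {
  cfg <- sim_config(state_E = c(0.25, 0.49), dwell_means = c(1, 1),
                    donor_only_frac = 0.3,
                    background_rates = c(DD = 50, AD = 50, AA = 50, DA = 10),
                    burst_duration_median_ms = 3, burst_rate_median_per_ms = 150)
  ps <- simulate_photon_stream(cfg, n_bursts = 400, rng_seed = 31)
  b <- search_bursts(ps, burst_params(500, 30, 120))
  b <- two_cde_scores(compute_es(correct_counts(b, correction_factors())), ps)
  species <- burst_species(b, ps)
  frac_donly_pre <- mean(species == "donor-only")
  expect_gt(frac_donly_pre, 0.1)

  kept <- filter_bursts(b, alex_2cde_max = 12)
  kept_species <- species[rownames(b) %in% rownames(kept)]
  frac_donly_post <- mean(kept_species == "donor-only")
  expect_lt(frac_donly_post, 0.05)
  expect_lte(frac_donly_post, frac_donly_pre)   # filtering never enriches contaminants
  expect_gt(nrow(kept), 0.5 * sum(species == "dual"))
})

test_that("filter thresholds behave at the extremes", {
  b <- data.frame(alex_2cde = c(2, 8, 30, NA), fret_2cde = c(9, 11, 40, NA),
                  S = c(0.5, 0.5, 0.9, 0.2))
  expect_equal(nrow(filter_bursts(b, alex_2cde_max = NULL)), 4L)   # disabled: identity
  expect_equal(nrow(filter_bursts(b, alex_2cde_max = 0)), 0L)      # zero: empty
  k <- filter_bursts(b, alex_2cde_max = 12, fret_2cde_range = c(8, 12))
  expect_equal(nrow(k), 2L)
  expect_equal(attr(k, "removed")[["alex_2cde"]], 2L)
})
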