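test_that("exponential MLE is the sample mean with tau/sqrt(n) error", {
  x <- rep(c(1, 2, 3), 4)
  f <- fit_exponential(x, method = "mle")
  expect_equal(f$tau, 2.0)
  expect_equal(f$se, 2.0 / sqrt(12))
})

test_that("MLE recovers a known exponential and is order/pooling invariant", {
  set.seed(71)
  x <- rexp(1000, rate = 1 / 2.1)
  f <- fit_exponential(x)
  expect_lt(abs(f$tau - 2.1), 0.2)
  f_shuffled <- fit_exponential(sample(x))
  expect_equal(f$tau, f_shuffled$tau)
  # pooling two halves equals fitting the pool
  expect_equal(mean(c(x[1:500], x[501:1000])), f$tau)
})

test_that("a noiseless histogram with the first bin dropped is fit exactly", {
  bw <- 0.04
  mids <- seq(bw * 1.5, 1.2, by = bw)      # first bin already excluded
  counts <- 500 * exp(-mids / 0.18)
  hf <- fit_dwell_histogram(mids, counts)
  expect_equal(hf$tau, 0.18, tolerance = 1e-6)
  expect_equal(hf$amplitude, 500, tolerance = 1e-4)
})

test_that("too few dwells is an error", {
  expect_error(fit_exponential(rexp(5)), ">= 10")
})

test_that("transition counting matches a hand-counted path", {
  ts <- transition_frequencies(list(c(1, 2, 3, 2, 1)), n_states = 3,
                               frame_period = 0.05)
  expect_equal(ts$counts[1, 2], 1L); expect_equal(ts$counts[2, 3], 1L)
  expect_equal(ts$counts[3, 2], 1L); expect_equal(ts$counts[2, 1], 1L)
  expect_equal(ts$counts[1, 3], 0L); expect_equal(ts$counts[3, 1], 0L)
  expect_equal(sum(ts$freq), 1)
  expect_equal(diag(ts$counts), rep(0L, 3))
  expect_equal(ts$time_in_state, c(2, 2, 1) * 0.05)
  empty <- transition_frequencies(list(), n_states = 2)
  expect_true(all(empty$counts == 0))
})

test_that("direct unbent<->fully-bent transitions are rare in decoded linear chains", {
  cfg <- sim_config(n_states = 3, state_E = c(0.32, 0.60, 0.75),
                    dwell_means = c(0.24, 0.31, 0.44),
                    topology = "linear-three-state",
                    e_noise_sd = 0.05, frame_period = 0.02)
  traces <- lapply(simulate_traces(cfg, 30, 20, rng_seed = 72), correct_trace)
  fit <- fit_hmm(traces, K = 3, n_restarts = 3, seed = 4)
  paths <- lapply(traces, function(tr) viterbi_path(fit, tr))
  tf <- transition_frequencies(paths, n_states = 3, frame_period = 0.02)
  expect_gt(tf$n_transitions, 1000)
  expect_lt((tf$counts[1, 3] + tf$counts[3, 1]) / tf$n_transitions, 0.05)
})

test_that("single-exit rates are exact reciprocals and rows satisfy sum(k) * tau = 1", {
  rm2 <- derive_rates(c(19.2, 0.18), topology = "two-state")
  expect_equal(rm2$k[1, 2], 1 / 19.2)
  expect_equal(rm2$k[2, 1], 1 / 0.18)
  tf <- transition_frequencies(list(c(1, 2, 1, 2, 3, 2, 3, 2, 1)), n_states = 3)
  rm3 <- derive_rates(c(0.24, 0.31, 0.44), tf, topology = "linear-three-state")
  for (i in 1:3)
    expect_equal(sum(rm3$k[i, ], na.rm = TRUE) * rm3$tau[i], 1, tolerance = 1e-12)
  # middle state with equal exit counts splits its exit rate evenly
  tf_eq <- transition_frequencies(list(c(2, 1, 2, 3, 2, 1, 2, 3)), n_states = 3)
  rm_eq <- derive_rates(c(0.24, 0.31, 0.44), tf_eq, "linear-three-state")
  expect_equal(rm_eq$k[2, 1], 0.5 / 0.31, tolerance = 1e-12)
  expect_equal(rm_eq$k[2, 3], 0.5 / 0.31, tolerance = 1e-12)
  expect_equal(round(rm_eq$k[2, 1], 2), 1.61)
})

test_that("forbidden-transition excess triggers a warning", {
  tf <- transition_frequencies(list(c(1, 3, 1, 3, 1, 2, 3)), n_states = 3)
  expect_warning(derive_rates(c(0.24, 0.31, 0.44), tf, "linear-three-state"),
                 "forbidden")
})

test_that("temperature factors are dwell ratios at integer reporting precision", {
  expect_equal(temperature_factor(5, 5)$ratio, 1)
  tf <- temperature_factor(19.2, 1.14)
  expect_equal(tf$ratio, 19.2 / 1.14)
  expect_equal(tf$approx, 17)
  expect_error(temperature_factor(-1, 2), "> 0")
})

test_that("survival fitting is exact on a noiseless decay and honours f(0) = 1", {
  s <- simulate_survival(732, seq(0, 3000, by = 600), n_molecules = Inf)
  expect_equal(s$fraction[1], 1)
  expect_equal(s$fraction[s$time_s == 600], exp(-600 / 732))
  f <- fit_survival(s)
  expect_equal(f$lifetime_s, 732, tolerance = 1e-8)
  expect_equal(f$lifetime_min, 12.2, tolerance = 1e-3)
  expect_equal(f$amplitude, 1)
  expect_error(fit_survival(c(0, 1, 2, 3), c(0.2, 0.2, 0.3, 0.9)),
               "non-decreasing")
  expect_error(fit_survival(c(0, 600), c(1, 0.5)), ">= 4")
})

test_that("binomial survival series recover the lifetime within 10% in >= 90% of replicates", {
  ok <- 0
  for (r in 1:200) {
    s <- simulate_survival(732, seq(0, 2400, by = 120), n_molecules = 500,
                           rng_seed = 5000 + r)
    f <- fit_survival(s)
    if (abs(f$lifetime_s - 732) <= 0.1 * 732) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.9)
})

test_that("Kd fitting is exact on the noiseless isotherm and robust to binomial noise", {
  t0 <- simulate_titration(48, c(0, 5, 15, 48, 150, 480, 1500), n_per_point = Inf)
  expect_equal(t0$fraction[t0$concentration_nM == 0], 0)
  expect_equal(t0$fraction[t0$concentration_nM == 48], 0.5)   # midpoint identity
  expect_equal(t0$fraction[t0$concentration_nM == 480], 10 / 11)
  f0 <- fit_kd(t0)
  expect_equal(f0$kd, 48, tolerance = 1e-8)
  tn <- simulate_titration(48, 10^seq(0, 3, length.out = 8),
                           n_per_point = 1000, rng_seed = 81)
  fn <- fit_kd(tn)
  expect_lt(abs(fn$kd - 48), 0.15 * 48)
  expect_error(simulate_titration(48, c(-1, 10)), ">= 0")
  expect_error(fit_kd(c(1, 2, 3, 4), c(0, 0, 0, 0)), "unidentifiable")
})
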