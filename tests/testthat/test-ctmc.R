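test_that("config validation rejects malformed ground truth", {
  expect_error(sim_config(state_E = c(0.25, 1.2)), "within \\(0, 1\\)")
  expect_error(sim_config(dwell_means = c(-1, 2)), "dwell_means")
  expect_error(sim_config(n_states = 4), "n_states")
  expect_error(sim_config(donor_only_frac = 0.7, acceptor_only_frac = 0.5),
               "sum to <= 1")
  expect_error(simulate_ctmc_path(sim_config(), duration = -5), "positive")
})

test_that("a zero exit rate yields a single dwell spanning the whole path", {
  cfg <- sim_config(dwell_means = c(Inf, 0.18))
  p <- simulate_ctmc_path(cfg, 100, rng_seed = 1, initial_state = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, 1L)
  expect_equal(p$t_entry, 0)
  expect_equal(p$t_exit, 100)
})

test_that("time-averaged occupancy matches the analytic stationary distribution", {
  cfg <- sim_config(dwell_means = c(19.2, 0.18))
  expect_equal(ctmc_generator(cfg)$pi[2], 0.18 / (0.18 + 19.2), tolerance = 1e-12)
  p <- simulate_ctmc_path(cfg, 10000, rng_seed = 42)
  occ <- sum((p$t_exit - p$t_entry)[p$state == 2]) / 10000
  n_cycles <- sum(p$state == 2)
  # relative SE of the bent-time fraction is ~1/sqrt(n_cycles)
  expect_lt(abs(occ - 0.18 / 19.38), 3 * (0.18 / 19.38) / sqrt(n_cycles))

  cfg3 <- sim_config(n_states = 3, state_E = c(0.32, 0.6, 0.75),
                     dwell_means = c(0.24, 0.31, 0.44),
                     topology = "linear-three-state")
  pi3 <- ctmc_generator(cfg3)$pi
  # occupancy proportional to (p_21 * tau1, tau2, (1 - p_21) * tau3)
  expect_equal(pi3, c(0.5 * 0.24, 0.31, 0.5 * 0.44) / sum(c(0.12, 0.31, 0.22)),
               tolerance = 1e-10)
  p3 <- simulate_ctmc_path(cfg3, 2000, rng_seed = 7)
  occ3 <- vapply(1:3, function(s)
    sum((p3$t_exit - p3$t_entry)[p3$state == s]), numeric(1)) / 2000
  expect_equal(occ3, pi3, tolerance = 0.1)
})

test_that("the linear three-state chain never jumps directly between 1 and 3", {
  cfg3 <- sim_config(n_states = 3, state_E = c(0.32, 0.6, 0.75),
                     dwell_means = c(0.24, 0.31, 0.44),
                     topology = "linear-three-state")
  p3 <- simulate_ctmc_path(cfg3, 800, rng_seed = 11)
  expect_gt(nrow(p3), 1000)
  jumps <- abs(diff(p3$state))
  expect_true(all(jumps == 1))
})

test_that("dwell durations are exponential with the configured means (KS test)", {
  cfg <- sim_config(dwell_means = c(0.5, 0.3), state_E = c(0.25, 0.49))
  p <- simulate_ctmc_path(cfg, 8100, rng_seed = 3)
  interior <- p[-c(1, nrow(p)), ]
  d1 <- (interior$t_exit - interior$t_entry)[interior$state == 1]
  expect_gt(length(d1), 9500)
  expect_gt(ks.test(d1, "pexp", rate = 1 / 0.5)$p.value, 0.01)
  d2 <- (interior$t_exit - interior$t_entry)[interior$state == 2]
  expect_gt(ks.test(d2, "pexp", rate = 1 / 0.3)$p.value, 0.01)
})

test_that("identical seeds reproduce paths bit-identically, different seeds decorrelate", {
  cfg <- sim_config()
  a <- simulate_ctmc_path(cfg, 500, rng_seed = 5)
  b <- simulate_ctmc_path(cfg, 500, rng_seed = 5)
  expect_identical(a, b)
  c <- simulate_ctmc_path(cfg, 500, rng_seed = 6)
  expect_false(isTRUE(all.equal(a$t_exit, c$t_exit)))
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_ctmc_path(sim_config(), 10, rng_seed = 1))
  expect_identical(runif(1), before)
})
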