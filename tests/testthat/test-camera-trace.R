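static_path <- function(state, duration) {
  structure(data.frame(state = state, t_entry = 0, t_exit = duration),
            duration = duration, class = c("ctmc_path", "data.frame"))
}

test_that("noiseless static traces are exact channel arithmetic", {
  cfg <- sim_config(e_noise_sd = 0, noise_sd = 0, total_intensity = 1000)
  tr <- simulate_camera_trace(static_path(2, 2), cfg, rng_seed = 1)
  expect_equal(nrow(tr), 100)                 # 2 s at 50 Hz
  expect_equal(tr$I_A, rep(490, 100))
  expect_equal(tr$I_D, rep(510, 100))
})

test_that("a state switch at a frame boundary produces exactly one step", {
  cfg <- sim_config(e_noise_sd = 0, noise_sd = 0)
  p <- structure(data.frame(state = c(1L, 2L), t_entry = c(0, 0.1),
                            t_exit = c(0.1, 0.2)),
                 duration = 0.2, class = c("ctmc_path", "data.frame"))
  tr <- simulate_camera_trace(p, cfg, rng_seed = 1)
  e <- tr$I_A / (tr$I_A + tr$I_D)
  expect_equal(e, rep(c(0.25, 0.49), each = 5))
  expect_equal(sum(abs(diff(e)) > 1e-9), 1L)
})

test_that("a mid-frame switch yields the time-weighted average E", {
  cfg <- sim_config(e_noise_sd = 0, noise_sd = 0)
  p <- structure(data.frame(state = c(1L, 2L), t_entry = c(0, 0.01),
                            t_exit = c(0.01, 0.02)),
                 duration = 0.02, class = c("ctmc_path", "data.frame"))
  tr <- simulate_camera_trace(p, cfg, rng_seed = 1)
  expect_equal(tr$I_A / (tr$I_A + tr$I_D), (0.25 + 0.49) / 2)
})

test_that("frame period longer than the path is rejected", {
  cfg <- sim_config(frame_period = 10)
  expect_error(simulate_camera_trace(static_path(1, 2), cfg), "empty trace")
})

test_that("per-frame E histograms recover the three configured state means", {
  cfg <- sim_config(n_states = 3, state_E = c(0.32, 0.60, 0.75),
                    dwell_means = c(0.24, 0.31, 0.44),
                    topology = "linear-three-state",
                    e_noise_sd = 0.05, frame_period = 0.02)
  traces <- simulate_traces(cfg, 100, 10, rng_seed = 13)
  e <- unlist(lapply(traces, function(tr) tr$I_A / (tr$I_A + tr$I_D)))
  dens <- density(e, bw = 0.01, n = 1024)
  # local maxima of the pooled E density
  y <- dens$y
  peak <- which(diff(sign(diff(y))) == -2) + 1
  peak <- peak[y[peak] > 0.1 * max(y)]
  modes <- dens$x[peak]
  for (m in c(0.32, 0.60, 0.75))
    expect_lt(min(abs(modes - m)), 0.02)
})

test_that("single-step bleaching drops the right channel", {
  cfg <- sim_config(dwell_means = c(Inf, 1), e_noise_sd = 0, noise_sd = 0,
                    bleach_mean_time = 5)
  # find a seed realization where the acceptor bleaches first, mid-trace
  tr <- NULL
  for (s in 1:50) {
    cand <- simulate_camera_trace(static_path(2, 30), cfg, rng_seed = s)
    th <- attr(cand, "truth")
    if (th$t_bleach_A > 2 && th$t_bleach_A + 2 < min(th$t_bleach_D, 28)) {
      tr <- cand; break
    }
  }
  expect_false(is.null(tr))
  th <- attr(tr, "truth")
  fA <- ceiling(th$t_bleach_A / 0.02) + 1
  fD <- floor(th$t_bleach_D / 0.02) - 1
  mid <- seq(fA + 1, min(fD, nrow(tr)))
  expect_equal(tr$I_A[mid], rep(0, length(mid)))       # acceptor dark
  expect_equal(tr$I_D[mid], rep(1000, length(mid)))    # donor de-quenched
  pre <- seq_len(max(1, fA - 2))
  expect_equal(tr$I_A[pre], rep(490, length(pre)))
})

test_that("trace simulation is seed-reproducible", {
  cfg <- sim_config()
  a <- simulate_traces(cfg, 3, 5, rng_seed = 2)
  b <- simulate_traces(cfg, 3, 5, rng_seed = 2)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
})
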