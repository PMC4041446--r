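#' Simulate a confocal ALEX photon stream
#'
#' Generates per-class Poisson background photons over the whole acquisition
#' plus `n_bursts` single-molecule burst envelopes. Each burst has a lognormal
#' duration and photon rate (rectangular envelope), carries one species
#' (dual-labelled in a conformational state drawn from the stationary
#' occupancy, donor-only, or acceptor-only) and emits photons whose
#' excitation-slot label follows from the absolute timestamp and the
#' alternation period. For a dual molecule the fraction of photons in
#' donor-excitation slots equals the configured stoichiometry `s_dual`, and a
#' donor-excited photon lands in the acceptor channel with probability
#' `E + leakage * (1 - E)`; direct excitation adds acceptor-channel photons in
#' donor slots at rate `direct_exc` times the molecule's acceptor-excitation
#' rate. Timestamps are strictly increasing integer microseconds.
#'
#' @param config A [sim_config()].
#' @param n_bursts Number of molecule transits (>= 0).
#' @param rng_seed Integer seed.
#' @param duration Acquisition length in seconds; default spaces bursts at
#'   about 20 per second.
#' @return A data.frame of class `photon_stream` with columns `timestamp_us`
#'   (integer), `channel` (`"donor"`/`"acceptor"`), `excitation_slot`
#'   (`"donor-exc"`/`"acceptor-exc"`) and `class` (`DD`/`AD`/`AA`/`DA`);
#'   attributes `alternation_period`, `duty`, `duration`, `background_rates`
#'   and `truth` (per-burst species, state and span).
#' @examples
#' cfg <- sim_config(background_rates = c(DD = 100, AD = 100, AA = 100, DA = 20))
#' ps <- simulate_photon_stream(cfg, n_bursts = 50, rng_seed = 3)
#' table(ps$class)
#' @export
simulate_photon_stream <- function(config, n_bursts, rng_seed = config$seed,
                                   duration = max(1, n_bursts / 20)) {
  validate_sim_config(config)
  if (n_bursts < 0) stopf("n_bursts must be >= 0")
  gen <- ctmc_generator(config)
  period <- config$alternation_period
  gate <- period * config$duty

  with_seed(rng_seed, {
    dur_us <- duration * 1e6
    ts_parts <- list(); ch_parts <- list()
    add <- function(t, c) {
      i <- length(ts_parts) + 1L
      ts_parts[[i]] <<- t
      ch_parts[[i]] <<- if (length(c) == 1L) rep(c, length(t)) else c
    }

    # background: homogeneous Poisson per detection class
    bg_channel <- c(DD = "donor", AD = "acceptor", AA = "acceptor", DA = "donor")
    bg_slotmax <- c(DD = TRUE, AD = TRUE, AA = FALSE, DA = FALSE)  # TRUE: donor slot
    for (cls in names(config$background_rates)) {
      n_bg <- rpois(1, config$background_rates[[cls]] * duration)
      if (n_bg == 0) next
      # place uniformly inside the matching excitation gate
      n_per <- dur_us / period
      base <- floor(runif(n_bg, 0, n_per)) * period
      # integer offsets so the excitation gate survives clock quantization
      off <- if (bg_slotmax[[cls]]) floor(runif(n_bg, 0, gate))
             else floor(runif(n_bg, gate, period))
      add(base + off, bg_channel[[cls]])
    }

    truth <- NULL
    if (n_bursts > 0) {
      b_dur <- rlnorm(n_bursts, log(config$burst_duration_median_ms * 1000),
                      config$burst_duration_sdlog)           # us
      b_rate <- rlnorm(n_bursts, log(config$burst_rate_median_per_ms / 1000),
                       config$burst_rate_sdlog)              # photons/us
      b_start <- runif(n_bursts, 0, pmax(dur_us - b_dur, 1))
      p_dual <- 1 - config$donor_only_frac - config$acceptor_only_frac
      species <- sample(c("dual", "donor-only", "acceptor-only"), n_bursts,
                        replace = TRUE,
                        prob = c(p_dual, config$donor_only_frac,
                                 config$acceptor_only_frac))
      state <- sample.int(config$n_states, n_bursts, replace = TRUE,
                          prob = gen$pi)
      for (b in seq_len(n_bursts)) {
        sp <- species[b]
        S <- switch(sp, dual = config$s_dual, `donor-only` = 1,
                    `acceptor-only` = 0)
        E <- if (sp == "dual") config$state_E[state[b]] else NA_real_
        # piecewise-constant rate: 2*rate*S in donor gates, 2*rate*(1-S) in
        # acceptor gates (acceptor-only additionally re-emits under direct
        # donor excitation at fraction direct_exc)
        r_d <- 2 * b_rate[b] * S
        r_a <- 2 * b_rate[b] * (1 - S)
        if (sp == "acceptor-only") r_d <- 2 * b_rate[b] * config$direct_exc
        r_max <- max(r_d, r_a)
        if (r_max <= 0) next
        n_cand <- rpois(1, r_max * b_dur[b])
        if (n_cand == 0) next
        t_cand <- floor(b_start[b] + runif(n_cand, 0, b_dur[b]))
        in_dgate <- (t_cand %% period) < gate
        acc <- runif(n_cand) < ifelse(in_dgate, r_d, r_a) / r_max
        t_b <- t_cand[acc]; dg <- in_dgate[acc]
        if (!length(t_b)) next
        ch_b <- character(length(t_b))
        # acceptor-excitation slot: acceptor emission (AA)
        ch_b[!dg] <- "acceptor"
        # donor-excitation slot
        p_acc <- switch(sp,
          dual = E + config$leakage * (1 - E),
          `donor-only` = config$leakage,
          `acceptor-only` = 1)
        ch_b[dg] <- ifelse(runif(sum(dg)) < p_acc, "acceptor", "donor")
        add(t_b, ch_b)
      }
      # direct-excitation extra AD photons for dual molecules
      if (config$direct_exc > 0) {
        for (b in which(species == "dual")) {
          n_dx <- rpois(1, config$direct_exc * b_rate[b] * (1 - config$s_dual) *
                          b_dur[b] * config$duty)
          if (n_dx == 0) next
          t_dx <- b_start[b] + runif(n_dx, 0, b_dur[b])
          t_dx <- (t_dx %/% period) * period + floor(runif(n_dx, 0, gate))
          add(t_dx, "acceptor")
        }
      }
      truth <- data.frame(burst = seq_len(n_bursts), species = species,
                          state = ifelse(species == "dual", state, NA_integer_),
                          start_us = b_start, stop_us = b_start + b_dur)
    }

    ts <- unlist(ts_parts, use.names = FALSE) %||% numeric(0)
    ch <- unlist(ch_parts, use.names = FALSE) %||% character(0)
    ord <- order(ts)
    ts <- make_strict_increasing(floor(ts[ord]))
    ch <- ch[ord]
    stream <- data.frame(timestamp_us = as.numeric(ts),
                         channel = ch, stringsAsFactors = FALSE)
    stream <- structure(stream, alternation_period = period, duty = config$duty,
                        duration = duration,
                        background_rates = config$background_rates,
                        truth = truth,
                        class = c("photon_stream", "data.frame"))
    classify_photons(stream)
  })
}
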