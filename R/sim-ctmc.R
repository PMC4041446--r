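#' Transition-rate generator of a configured conformational model
#'
#' Builds the continuous-time Markov chain implied by a [sim_config()]:
#' exit rate of state i is `1 / dwell_means[i]` and the embedded jump
#' probabilities follow the declared topology (two-state flip-flop, or the
#' linear chain 1 <-> 2 <-> 3 with middle-state branching `p_21`).
#'
#' @param config A [sim_config()].
#' @return A list with the rate matrix `Q` (off-diagonal k_ij in 1/s), the
#'   embedded jump matrix `P`, and the stationary occupancy `pi`.
#' @export
ctmc_generator <- function(config) {
  validate_sim_config(config)
  K <- config$n_states
  rate <- 1 / config$dwell_means
  P <- matrix(0, K, K)
  if (config$topology == "two-state") {
    P[1, 2] <- 1; P[2, 1] <- 1
  } else {
    P[1, 2] <- 1
    P[3, 2] <- 1
    P[2, 1] <- config$p_21
    P[2, 3] <- 1 - config$p_21
  }
  Q <- P * rate
  diag(Q) <- -rate
  # time-averaged occupancy: embedded-chain frequencies weighted by dwell means
  nu <- embedded_stationary(P)
  if (any(is.infinite(config$dwell_means))) {
    pi <- as.numeric(is.infinite(config$dwell_means))
    pi <- pi / sum(pi)           # absorbing state(s) carry all occupancy
  } else {
    pi <- nu * config$dwell_means
    pi <- pi / sum(pi)
  }
  list(Q = Q, P = P, pi = pi)
}

# stationary distribution of the embedded jump chain (left eigenvector)
embedded_stationary <- function(P) {
  K <- nrow(P)
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  as.numeric(qr.solve(A, b))
}

#' Simulate a continuous-time conformational state path
#'
#' Draws exponentially distributed dwells with the configured means and jumps
#' according to the configured topology, until `duration` seconds are covered.
#' The final dwell is truncated at `duration` (and flagged), so the path tiles
#' `[0, duration]` exactly.
#'
#' @param config A [sim_config()].
#' @param duration Path length in seconds (> 0).
#' @param rng_seed Integer seed; defaults to the config seed.
#' @param initial_state Starting state, or `NULL` to draw from the stationary
#'   occupancy.
#' @return A data.frame of class `ctmc_path` with columns `state`,
#'   `t_entry`, `t_exit` (seconds) and attribute `duration`.
#' @examples
#' cfg <- sim_config()
#' path <- simulate_ctmc_path(cfg, duration = 60, rng_seed = 7)
#' tapply(path$t_exit - path$t_entry, path$state, sum) / 60  # occupancy
#' @export
simulate_ctmc_path <- function(config, duration, rng_seed = config$seed,
                               initial_state = NULL) {
  validate_sim_config(config)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stopf("invalid config: duration must be a single positive number")
  gen <- ctmc_generator(config)
  with_seed(rng_seed, {
    state <- if (is.null(initial_state)) {
      sample.int(config$n_states, 1, prob = gen$pi)
    } else as.integer(initial_state)
    cap <- 256L
    states <- integer(cap); entries <- numeric(cap); exits <- numeric(cap)
    n <- 0L
    t <- 0
    while (t < duration) {
      m <- config$dwell_means[state]
      dwell <- if (is.finite(m)) rexp(1, rate = 1 / m) else Inf
      t_exit <- min(t + dwell, duration)
      n <- n + 1L
      if (n > cap) {  # amortized doubling
        cap <- cap * 2L
        length(states) <- cap; length(entries) <- cap; length(exits) <- cap
      }
      states[n] <- state; entries[n] <- t; exits[n] <- t_exit
      t <- t_exit
      if (t >= duration) break
      state <- sample.int(config$n_states, 1, prob = gen$P[state, ])
    }
    structure(data.frame(state = states[seq_len(n)], t_entry = entries[seq_len(n)],
                         t_exit = exits[seq_len(n)]),
              duration = duration, class = c("ctmc_path", "data.frame"))
  })
}
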