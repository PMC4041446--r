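#' Ground-truth configuration for the synthetic-data generator
#'
#' Collects every parameter the simulators need: the conformational model
#' (number of states, per-state proximity ratios, mean dwell times, topology),
#' spectral crosstalk, background and noise, the excitation alternation and
#' camera timing, photobleaching, and contaminant species fractions. The
#' defaults describe the archaeal two-state system at room temperature:
#' unbent/bent proximity ratios 0.25/0.49 with mean dwell times 19.2 s
#' (unbent) and 0.18 s (bent).
#'
#' @param n_states Number of conformational states (2 or 3).
#' @param state_E Proximity ratio of each state, strictly inside (0, 1),
#'   ordered to match `dwell_means`.
#' @param dwell_means Mean dwell time of each state in seconds (`Inf` pins a
#'   state permanently).
#' @param topology `"two-state"` or `"linear-three-state"`. The linear chain
#'   is unbent (1) - intermediate (2) - fully bent (3); direct 1<->3
#'   transitions are forbidden by construction.
#' @param p_21 For the linear three-state chain, the probability that an exit
#'   from the middle state goes to state 1 (the remainder goes to state 3).
#' @param leakage Fraction of donor photons detected in the acceptor channel.
#' @param direct_exc Fraction of acceptor-excitation-equivalent signal excited
#'   directly by the donor laser.
#' @param background_rates Named photon background rates in photons/s for the
#'   detection classes `DD`, `AD`, `AA`, `DA`.
#' @param alternation_period Excitation alternation period in microseconds;
#'   the donor laser occupies the first `duty` fraction of each period.
#' @param duty Donor-excitation duty cycle within the alternation period.
#' @param frame_period Camera frame period in seconds.
#' @param total_intensity Total (donor + acceptor) photons per frame for a
#'   surface-immobilized molecule.
#' @param noise_sd Additive Gaussian camera noise per channel (counts/frame).
#' @param e_noise_sd Gaussian noise applied directly to the per-frame apparent
#'   proximity ratio (models the combined shot/camera noise seen in E space).
#' @param bleach_mean_time Mean single-step photobleaching time per
#'   fluorophore in seconds, or `NULL` for no bleaching. Donor and acceptor
#'   bleach independently.
#' @param donor_only_frac,acceptor_only_frac Fractions of contaminant
#'   donor-only / acceptor-only molecules in diffusing-molecule simulations.
#' @param s_dual Stoichiometry of the dual-labelled species (fraction of a
#'   molecule's photons emitted during donor-excitation slots).
#' @param burst_duration_median_ms,burst_duration_sdlog Lognormal burst
#'   envelope duration (median, log-sd) for diffusing molecules.
#' @param burst_rate_median_per_ms,burst_rate_sdlog Lognormal per-burst photon
#'   rate (median photons/ms, log-sd).
#' @param seed Default RNG seed used when a simulator is called without one.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config()                     # archaeal two-state defaults
#' cfg3 <- sim_config(
#'   n_states = 3, state_E = c(0.32, 0.60, 0.75),
#'   dwell_means = c(0.24, 0.31, 0.44), topology = "linear-three-state")
#' @export
sim_config <- function(n_states = 2,
                       state_E = c(0.25, 0.49),
                       dwell_means = c(19.2, 0.18),
                       topology = c("two-state", "linear-three-state"),
                       p_21 = 0.5,
                       leakage = 0,
                       direct_exc = 0,
                       background_rates = c(DD = 250, AD = 250, AA = 250, DA = 250),
                       alternation_period = 100,
                       duty = 0.5,
                       frame_period = 0.02,
                       total_intensity = 1000,
                       noise_sd = 0,
                       e_noise_sd = 0.07,
                       bleach_mean_time = NULL,
                       donor_only_frac = 0,
                       acceptor_only_frac = 0,
                       s_dual = 0.5,
                       burst_duration_median_ms = 1,
                       burst_duration_sdlog = 0.4,
                       burst_rate_median_per_ms = 50,
                       burst_rate_sdlog = 0.4,
                       seed = 1L) {
  topology <- match.arg(topology)
  if (n_states == 3 && topology == "two-state") topology <- "linear-three-state"
  cfg <- structure(list(
    n_states = as.integer(n_states), state_E = as.numeric(state_E),
    dwell_means = as.numeric(dwell_means), topology = topology, p_21 = p_21,
    leakage = leakage, direct_exc = direct_exc,
    background_rates = background_rates,
    alternation_period = alternation_period, duty = duty,
    frame_period = frame_period, total_intensity = total_intensity,
    noise_sd = noise_sd, e_noise_sd = e_noise_sd,
    bleach_mean_time = bleach_mean_time,
    donor_only_frac = donor_only_frac, acceptor_only_frac = acceptor_only_frac,
    s_dual = s_dual,
    burst_duration_median_ms = burst_duration_median_ms,
    burst_duration_sdlog = burst_duration_sdlog,
    burst_rate_median_per_ms = burst_rate_median_per_ms,
    burst_rate_sdlog = burst_rate_sdlog,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!cfg$n_states %in% c(2L, 3L))
    stopf("invalid config: n_states must be 2 or 3, got %s", cfg$n_states)
  if (length(cfg$state_E) != cfg$n_states ||
      length(cfg$dwell_means) != cfg$n_states)
    stopf("invalid config: state_E and dwell_means must each have length n_states (%d)",
          cfg$n_states)
  if (any(cfg$state_E <= 0 | cfg$state_E >= 1))
    stopf("invalid config: state_E values must lie strictly within (0, 1)")
  if (any(cfg$dwell_means <= 0))
    stopf("invalid config: all dwell_means must be > 0")
  if (cfg$topology == "linear-three-state" && cfg$n_states != 3L)
    stopf("invalid config: linear-three-state topology requires n_states = 3")
  if (cfg$p_21 < 0 || cfg$p_21 > 1)
    stopf("invalid config: p_21 must be in [0, 1]")
  for (f in c("leakage", "direct_exc", "donor_only_frac", "acceptor_only_frac")) {
    v <- cfg[[f]]
    if (v < 0 || v >= 1) stopf("invalid config: %s must be in [0, 1)", f)
  }
  if (cfg$donor_only_frac + cfg$acceptor_only_frac > 1)
    stopf("invalid config: contaminant fractions must sum to <= 1")
  if (any(cfg$background_rates < 0))
    stopf("invalid config: background rates must be >= 0")
  if (!all(c("DD", "AD", "AA", "DA") %in% names(cfg$background_rates)))
    stopf("invalid config: background_rates needs names DD, AD, AA, DA")
  if (cfg$alternation_period <= 0 || cfg$duty <= 0 || cfg$duty >= 1)
    stopf("invalid config: alternation_period > 0 and duty in (0, 1) required")
  if (cfg$frame_period <= 0) stopf("invalid config: frame_period must be > 0")
  if (cfg$total_intensity <= 0) stopf("invalid config: total_intensity must be > 0")
  if (!is.null(cfg$bleach_mean_time) && cfg$bleach_mean_time <= 0)
    stopf("invalid config: bleach_mean_time must be > 0 or NULL")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s, %d states\n", x$topology, x$n_states))
  cat("  state E:     ", paste(format(x$state_E), collapse = ", "), "\n")
  cat("  dwell means: ", paste(format(x$dwell_means), collapse = ", "), "s\n")
  cat(sprintf("  frame %.0f ms, alternation %g us, E-noise sd %g\n",
              1000 * x$frame_period, x$alternation_period, x$e_noise_sd))
  invisible(x)
}
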