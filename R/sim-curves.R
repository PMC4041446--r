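#' Simulate an equilibrium bent-fraction titration
#'
#' At concentration `c` the bent fraction is drawn
#' `Binomial(n_per_point, c / (c + kd)) / n_per_point` (pseudo-first-order
#' Langmuir isotherm: protein in large excess over the 10 pM DNA).
#' `n_per_point = Inf` returns the noiseless isotherm.
#'
#' @param kd Dissociation constant in nM (> 0).
#' @param concentrations Protein concentrations in nM (>= 0).
#' @param n_per_point Molecules scored per concentration.
#' @param rng_seed Integer seed.
#' @return A data.frame of class `titration_curve`: `concentration_nM`, `n`,
#'   `n_bent`, `fraction`.
#' @examples
#' simulate_titration(48, c(0, 48, 480), n_per_point = Inf)
#' @export
simulate_titration <- function(kd, concentrations, n_per_point = 1000,
                               rng_seed = 1L) {
  if (kd <= 0) stopf("kd must be > 0")
  if (any(concentrations < 0)) stopf("concentrations must be >= 0")
  p <- concentrations / (concentrations + kd)
  p[concentrations == 0] <- 0
  if (is.infinite(n_per_point)) {
    frac <- p
    n_bent <- rep(NA_real_, length(p))
  } else {
    frac <- with_seed(rng_seed, rbinom(length(p), n_per_point, p)) / n_per_point
    n_bent <- frac * n_per_point
  }
  structure(data.frame(concentration_nM = concentrations, n = n_per_point,
                       n_bent = n_bent, fraction = frac),
            kd = kd, class = c("titration_curve", "data.frame"))
}

#' Simulate a complex-survival series
#'
#' First-order decay: the surviving fraction at time `t` is
#' `Binomial(n_molecules, exp(-t / lifetime)) / n_molecules`.
#' `n_molecules = Inf` returns the noiseless decay.
#'
#' @param lifetime Mean complex lifetime in seconds (> 0).
#' @param sample_times Observation times in seconds.
#' @param n_molecules Complexes observed at t = 0.
#' @param rng_seed Integer seed.
#' @return A data.frame of class `survival_series`: `time_s`, `n_surviving`,
#'   `fraction`.
#' @examples
#' simulate_survival(732, c(0, 366, 732), n_molecules = Inf)
#' @export
simulate_survival <- function(lifetime, sample_times, n_molecules = 500,
                              rng_seed = 1L) {
  if (lifetime <= 0) stopf("lifetime must be > 0")
  p <- exp(-sample_times / lifetime)
  if (is.infinite(n_molecules)) {
    frac <- p
    n_surv <- rep(NA_real_, length(p))
  } else {
    n_surv <- with_seed(rng_seed, rbinom(length(p), n_molecules, p))
    frac <- n_surv / n_molecules
  }
  structure(data.frame(time_s = sample_times, n_surviving = n_surv,
                       fraction = frac),
            lifetime = lifetime, class = c("survival_series", "data.frame"))
}
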