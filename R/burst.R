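#' Label photons by detection class
#'
#' Assigns each photon its ALEX detection class from the detector channel and
#' the excitation slot implied by `timestamp mod alternation_period`: the
#' donor laser occupies the first `duty` fraction of each period. Classes are
#' `DD` (donor emission, donor excitation), `AD` (acceptor emission, donor
#' excitation), `AA` (acceptor emission, acceptor excitation) and `DA` (donor
#' emission, acceptor excitation; retained but excluded from E/S).
#'
#' @param stream A `photon_stream` data.frame with `timestamp_us` (sorted
#'   strictly ascending) and `channel`.
#' @param alternation_period Alternation period in microseconds (default: the
#'   stream attribute, else 100).
#' @param duty Donor-excitation duty cycle (default: stream attribute, else 0.5).
#' @return The stream with `excitation_slot` and `class` columns.
#' @export
classify_photons <- function(stream,
                             alternation_period = attr(stream, "alternation_period") %||% 100,
                             duty = attr(stream, "duty") %||% 0.5) {
  ts <- stream$timestamp_us
  if (is.unsorted(ts, strictly = TRUE))
    stopf("photon timestamps must be sorted strictly ascending")
  if (!all(stream$channel %in% c("donor", "acceptor")))
    stopf("unknown channel codes: %s",
          paste(setdiff(unique(stream$channel), c("donor", "acceptor")), collapse = ", "))
  donor_slot <- (ts %% alternation_period) < alternation_period * duty
  stream$excitation_slot <- ifelse(donor_slot, "donor-exc", "acceptor-exc")
  stream$class <- ifelse(donor_slot,
                         ifelse(stream$channel == "donor", "DD", "AD"),
                         ifelse(stream$channel == "donor", "DA", "AA"))
  attr(stream, "alternation_period") <- alternation_period
  attr(stream, "duty") <- duty
  if (!inherits(stream, "photon_stream"))
    class(stream) <- c("photon_stream", class(stream))
  stream
}

#' Burst-search parameters (T/M/N criterion)
#'
#' A photon qualifies if at least `M` photons (itself included) fall within a
#' window of length `T` microseconds around it; a burst is a maximal run of at
#' least `N` consecutive qualifying photons. The values used for the
#' Cy3b/ATTO647n dye pair are `T = 500, M = 30, N = 120`; for
#' ATTO532/ATTO647n, `T = 500, M = 10, N = 50`.
#'
#' @param T_us Window length in microseconds.
#' @param M Minimum photons within the window.
#' @param N Minimum consecutive qualifying photons per burst.
#' @return A `burst_params` list.
#' @export
burst_params <- function(T_us = 500, M = 30, N = 120) {
  if (any(c(T_us, M, N) <= 0) || any(c(T_us, M, N) != round(c(T_us, M, N))))
    stopf("T, M, N must be positive integers")
  if (M > N) stopf("burst search requires M <= N")
  structure(list(T_us = T_us, M = M, N = N), class = "burst_params")
}

#' Sliding-window burst search
#'
#' Runs the T/M/N criterion on all photons pooled across detection classes.
#' By default the window is centered on each photon; `anchor = "start"` counts
#' photons in `[t, t + T)` instead.
#'
#' @param stream A classified `photon_stream`.
#' @param params A [burst_params()].
#' @param anchor Window convention, `"center"` (default) or `"start"`.
#' @return A data.frame of class `burst_table`: photon index range, start/stop
#'   times, duration and raw per-class counts of each burst, ordered and
#'   disjoint. Zero rows if no burst qualifies.
#' @export
search_bursts <- function(stream, params = burst_params(),
                          anchor = c("center", "start")) {
  anchor <- match.arg(anchor)
  ts <- stream$timestamp_us
  n <- length(ts)
  empty <- data.frame(i_start = integer(0), i_stop = integer(0),
                      start_us = numeric(0), stop_us = numeric(0),
                      duration_s = numeric(0), n_photons = integer(0),
                      DD = integer(0), AD = integer(0), AA = integer(0),
                      DA = integer(0))
  if (n == 0)
    return(structure(empty, params = params, class = c("burst_table", "data.frame")))
  if (is.unsorted(ts, strictly = TRUE))
    stopf("photon timestamps must be sorted strictly ascending")

  half <- params$T_us / 2
  # photons with timestamp <= x: findInterval on the strictly sorted stamps
  cnt <- if (anchor == "center") {
    findInterval(ts + half, ts) - findInterval(ts - half - 1e-9, ts)
  } else {
    findInterval(ts + params$T_us - 1e-9, ts) - findInterval(ts - 1e-9, ts)
  }
  qual <- cnt >= params$M
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$N
  if (!any(keep))
    return(structure(empty, params = params, class = c("burst_table", "data.frame")))
  i_start <- starts[keep]; i_stop <- ends[keep]
  cls <- stream$class
  counts <- vapply(seq_along(i_start), function(b) {
    idx <- cls[i_start[b]:i_stop[b]]
    c(DD = sum(idx == "DD"), AD = sum(idx == "AD"),
      AA = sum(idx == "AA"), DA = sum(idx == "DA"))
  }, integer(4))
  out <- data.frame(i_start = i_start, i_stop = i_stop,
                    start_us = ts[i_start], stop_us = ts[i_stop],
                    duration_s = (ts[i_stop] - ts[i_start]) * 1e-6,
                    n_photons = i_stop - i_start + 1L,
                    DD = counts["DD", ], AD = counts["AD", ],
                    AA = counts["AA", ], DA = counts["DA", ])
  structure(out, params = params, class = c("burst_table", "data.frame"))
}

#' Background and crosstalk correction of burst counts
#'
#' Subtracts the expected background photons (rate times burst duration) from
#' each class count, flooring at zero. With `apply_crosstalk = TRUE` the
#' donor-excited acceptor count is additionally corrected for donor leakage
#' and direct acceptor excitation:
#' `F_AD <- F_AD - leakage * F_DD - direct_exc * F_AA`, floored at zero.
#'
#' @param bursts A `burst_table`.
#' @param corrections List/vector with `leakage`, `direct_exc` and
#'   `background_rates` (named photons/s per class); see [correction_factors()].
#' @param apply_crosstalk Apply the leakage/direct-excitation correction
#'   (default `FALSE` for confocal bursts).
#' @return The burst table with corrected columns `F_DD`, `F_AD`, `F_AA`.
#' @export
correct_counts <- function(bursts, corrections = correction_factors(),
                           apply_crosstalk = FALSE) {
  bg <- corrections$background_rates
  if (any(bg < 0)) stopf("background rates must be >= 0")
  dur <- pmax(bursts$duration_s, 1e-6)
  F_DD <- pmax(bursts$DD - bg[["DD"]] * dur, 0)
  F_AD <- pmax(bursts$AD - bg[["AD"]] * dur, 0)
  F_AA <- pmax(bursts$AA - bg[["AA"]] * dur, 0)
  if (apply_crosstalk)
    F_AD <- pmax(F_AD - corrections$leakage * F_DD -
                   corrections$direct_exc * F_AA, 0)
  bursts$F_DD <- F_DD; bursts$F_AD <- F_AD; bursts$F_AA <- F_AA
  attr(bursts, "corrections") <- corrections
  attr(bursts, "crosstalk_applied") <- apply_crosstalk
  bursts
}

#' Crosstalk and background correction factors
#'
#' @param leakage Donor-to-acceptor-channel leakage fraction in `[0, 1)`.
#' @param direct_exc Direct-acceptor-excitation fraction in `[0, 1)`.
#' @param background_rates Named background rates (photons/s) for DD, AD, AA.
#' @return A `correction_factors` list.
#' @export
correction_factors <- function(leakage = 0, direct_exc = 0,
                               background_rates = c(DD = 0, AD = 0, AA = 0)) {
  if (leakage < 0 || leakage >= 1 || direct_exc < 0 || direct_exc >= 1)
    stopf("leakage and direct_exc must be in [0, 1)")
  if (any(background_rates < 0)) stopf("background rates must be >= 0")
  structure(list(leakage = leakage, direct_exc = direct_exc,
                 background_rates = background_rates),
            class = "correction_factors")
}

#' Proximity ratio E and stoichiometry S from corrected counts
#'
#' `E = F_AD / (F_AD + F_DD)` and `S = (F_AD + F_DD) / (F_AD + F_DD + F_AA)`.
#' Zero denominators give `NA` and set the `es_undefined` flag.
#'
#' @param bursts A corrected `burst_table`, or a numeric F_DD with `F_AD` and
#'   `F_AA` supplied separately.
#' @param F_AD,F_AA Counts when `bursts` is numeric `F_DD`.
#' @return The burst table with `E`, `S` and `es_undefined` columns (or a
#'   two-column data.frame for numeric input).
#' @examples
#' compute_es(150, 50, 100)  # E = 0.25, S = 2/3
#' @export
compute_es <- function(bursts, F_AD = NULL, F_AA = NULL) {
  if (is.numeric(bursts)) {
    bursts <- data.frame(F_DD = bursts, F_AD = F_AD, F_AA = F_AA)
    plain <- TRUE
  } else plain <- FALSE
  if (any(bursts$F_DD < 0 | bursts$F_AD < 0 | bursts$F_AA < 0, na.rm = TRUE))
    stopf("counts must be >= 0")
  dex <- bursts$F_AD + bursts$F_DD
  tot <- dex + bursts$F_AA
  E <- ifelse(dex > 0, bursts$F_AD / dex, NA_real_)
  S <- ifelse(tot > 0, dex / tot, NA_real_)
  bursts$E <- E
  bursts$S <- S
  bursts$es_undefined <- !is.finite(E) | !is.finite(S)
  if (plain) bursts[, c("E", "S", "es_undefined")] else bursts
}

#' Estimate class-wise background rates from a stream
#'
#' Mean photon rate per detection class with burst regions excised, iterated
#' once: bursts found on the raw stream are removed, rates re-estimated.
#'
#' @param stream A classified `photon_stream`.
#' @param params [burst_params()] used to excise bursts.
#' @return Named rates (photons/s) for DD, AD, AA, DA.
#' @export
estimate_background <- function(stream, params = burst_params()) {
  dur <- attr(stream, "duration") %||%
    (diff(range(stream$timestamp_us)) * 1e-6)
  class_rates <- function(s, d) {
    tab <- table(factor(s$class, levels = c("DD", "AD", "AA", "DA")))
    setNames(as.numeric(tab) / max(d, 1e-9), names(tab))
  }
  bursts <- search_bursts(stream, params)
  if (nrow(bursts) == 0) return(class_rates(stream, dur))
  in_burst <- rep(FALSE, nrow(stream))
  for (b in seq_len(nrow(bursts)))
    in_burst[bursts$i_start[b]:bursts$i_stop[b]] <- TRUE
  class_rates(stream[!in_burst, , drop = FALSE], dur - sum(bursts$duration_s))
}
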