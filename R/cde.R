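#' ALEX-2CDE and FRET-2CDE burst scores
#'
#' Kernel-density burst statistics that score within-burst brightness
#' fluctuation with an exponential kernel `exp(-|dt|/tau)`.
#'
#' ALEX-2CDE compares the local densities of donor-excitation and
#' acceptor-excitation photons at each other's arrival times:
#' `ALEX-2CDE = 100 - 50 * (BR_DA + BR_AD)` with
#' `BR_DA = (1/N_Dex) * sum_{i in Aex} KDE_i^Dex / KDE_i^Aex` (and the mirror
#' term). A static dual-labelled burst, whose two excitation streams are
#' interleaved at stationary rates, scores near 0; donor-only or
#' acceptor-only bursts, where one stream is essentially absent, score high.
#'
#' FRET-2CDE measures FRET-efficiency fluctuation within the
#' donor-excitation stream: `FRET-2CDE = 110 - 100 * (<E>_D + <1-E>_A)`, where
#' `<E>_D` averages `KDE^AD / (KDE^AD + nbKDE^DD)` over DD photons and
#' `<1-E>_A` averages `KDE^DD / (KDE^DD + nbKDE^AD)` over AD photons, with the
#' no-burst correction `nbKDE^X(t_i) = (1 + 2/N_X) * sum_{j != i} k(t_i-t_j)`.
#' A FRET-static burst scores about 10; bleaching or blinking mid-burst pushes
#' the score away from 10.
#'
#' @param bursts A `burst_table` from [search_bursts()].
#' @param stream The classified `photon_stream` the bursts were found in.
#' @param kde_time_constant Kernel time constant tau in microseconds.
#' @return The burst table with `alex_2cde` and `fret_2cde` columns (`NA`
#'   when a required photon class is absent; such bursts are flagged in
#'   `cde_undefined`).
#' @export
two_cde_scores <- function(bursts, stream, kde_time_constant = 100) {
  tau <- kde_time_constant
  ts <- stream$timestamp_us
  cls <- stream$class
  n_b <- nrow(bursts)
  alex <- fret <- rep(NA_real_, n_b)
  for (b in seq_len(n_b)) {
    idx <- bursts$i_start[b]:bursts$i_stop[b]
    t_all <- ts[idx]; c_all <- cls[idx]
    t_dex <- t_all[c_all %in% c("DD", "AD")]
    t_aex <- t_all[c_all %in% c("AA", "DA")]
    t_dd <- t_all[c_all == "DD"]
    t_ad <- t_all[c_all == "AD"]

    if (length(t_dex) > 0 && length(t_aex) > 0) {
      kde_dex_at_aex <- exp_kde(t_aex, t_dex, tau)
      kde_aex_at_aex <- exp_kde(t_aex, t_aex, tau)   # self included
      kde_aex_at_dex <- exp_kde(t_dex, t_aex, tau)
      kde_dex_at_dex <- exp_kde(t_dex, t_dex, tau)
      br_da <- sum(kde_dex_at_aex / kde_aex_at_aex) / length(t_dex)
      br_ad <- sum(kde_aex_at_dex / kde_dex_at_dex) / length(t_aex)
      alex[b] <- 100 - 50 * (br_da + br_ad)
    }
    if (length(t_dd) > 1 && length(t_ad) > 1) {
      n_d <- length(t_dd); n_a <- length(t_ad)
      kde_ad_at_dd <- exp_kde(t_dd, t_ad, tau)
      nb_dd <- (1 + 2 / n_d) * (exp_kde(t_dd, t_dd, tau) - 1)
      kde_dd_at_ad <- exp_kde(t_ad, t_dd, tau)
      nb_ad <- (1 + 2 / n_a) * (exp_kde(t_ad, t_ad, tau) - 1)
      e_d <- mean(kde_ad_at_dd / pmax(kde_ad_at_dd + nb_dd, 1e-12))
      e_a <- mean(kde_dd_at_ad / pmax(kde_dd_at_ad + nb_ad, 1e-12))
      fret[b] <- 110 - 100 * (e_d + e_a)
    }
  }
  bursts$alex_2cde <- alex
  bursts$fret_2cde <- fret
  bursts$cde_undefined <- !is.finite(alex)
  bursts
}

#' Threshold filtering of scored bursts
#'
#' Applies the enabled thresholds (`NULL` disables a criterion) and reports
#' how many bursts each criterion removed (attribute `removed`).
#'
#' @param bursts A scored `burst_table` (after [compute_es()] and/or
#'   [two_cde_scores()]).
#' @param alex_2cde_max Keep bursts with `alex_2cde <=` this value (the
#'   working threshold is 12).
#' @param fret_2cde_range Keep bursts with `fret_2cde` inside `[lo, hi]`
#'   (e.g. `c(8, 12)`), or `NULL` to disable.
#' @param s_range Keep bursts with stoichiometry inside `[lo, hi]`, or `NULL`.
#' @param drop_undefined Drop bursts whose required scores are undefined.
#' @return The filtered burst table; attribute `removed` holds per-criterion
#'   removal counts.
#' @export
filter_bursts <- function(bursts, alex_2cde_max = 12, fret_2cde_range = NULL,
                          s_range = NULL, drop_undefined = TRUE) {
  keep <- rep(TRUE, nrow(bursts))
  removed <- c()
  apply_crit <- function(ok, name) {
    n_before <- sum(keep)
    keep <<- keep & ok
    removed[[name]] <<- n_before - sum(keep)
  }
  if (!is.null(alex_2cde_max)) {
    ok <- if (drop_undefined) !is.na(bursts$alex_2cde) & bursts$alex_2cde <= alex_2cde_max
          else is.na(bursts$alex_2cde) | bursts$alex_2cde <= alex_2cde_max
    apply_crit(ok, "alex_2cde")
  }
  if (!is.null(fret_2cde_range)) {
    ok <- !is.na(bursts$fret_2cde) &
      bursts$fret_2cde >= fret_2cde_range[1] &
      bursts$fret_2cde <= fret_2cde_range[2]
    if (!drop_undefined) ok <- ok | is.na(bursts$fret_2cde)
    apply_crit(ok, "fret_2cde")
  }
  if (!is.null(s_range) && "S" %in% names(bursts)) {
    ok <- !is.na(bursts$S) & bursts$S >= s_range[1] & bursts$S <= s_range[2]
    apply_crit(ok, "stoichiometry")
  }
  out <- bursts[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "params") <- attr(bursts, "params")
  class(out) <- class(bursts)
  out
}
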