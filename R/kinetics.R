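#' Mono-exponential fit of dwell times
#'
#' Two estimators of the mean dwell time tau are provided. `"mle"`: the
#' maximum-likelihood estimate for exponential data, `tau = mean(dwells)`
#' with `SE = tau / sqrt(n)`. `"histogram"`: least-squares fit of
#' `A * exp(-t / tau)` to binned dwell counts, with the first bin dropped as
#' a guard against events missed at the camera's temporal resolution
#' (default bin width: two frame periods).
#'
#' @param dwells Numeric dwell durations in seconds, or a `dwell_set` from
#'   [extract_dwells()] (censored dwells excluded unless
#'   `include_censored = TRUE`).
#' @param method `"mle"` or `"histogram"`.
#' @param state When `dwells` is a `dwell_set`, the state to fit.
#' @param bin_width Histogram bin width in seconds (histogram method).
#' @param frame_period Used for the default bin width (2 frame periods).
#' @param include_censored Include observation-window-truncated dwells.
#' @return An object of class `dwell_fit`: `tau` (s), `se`, `method`, `n`.
#' @examples
#' fit_exponential(c(1, 2, 3))  # tau = 2 s
#' @export
fit_exponential <- function(dwells, method = c("mle", "histogram"),
                            state = NULL, bin_width = NULL,
                            frame_period = NULL, include_censored = FALSE) {
  method <- match.arg(method)
  if (inherits(dwells, "dwell_set")) {
    d <- dwells
    if (!is.null(state)) d <- d[d$state == state, , drop = FALSE]
    if (!include_censored) d <- d[!d$censored, , drop = FALSE]
    x <- d$duration_s
  } else {
    x <- as.numeric(dwells)
  }
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 10)
    stopf("exponential fit needs >= 10 uncensored dwells, got %d", length(x))

  if (method == "mle") {
    tau <- mean(x)
    se <- tau / sqrt(length(x))
  } else {
    bw <- bin_width %||% (if (!is.null(frame_period)) 2 * frame_period else
      diff(quantile(x, c(0.05, 0.95))) / 15)
    breaks <- seq(0, max(x) + bw, by = bw)
    cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)
    mids <- cnt$mids[-1]      # first bin dropped (missed-event guard)
    counts <- cnt$counts[-1]
    hf <- fit_dwell_histogram(mids, counts)
    tau <- hf$tau; se <- hf$se
  }
  structure(list(tau = tau, se = se, method = method, n = length(x),
                 state = state), class = "dwell_fit")
}

#' Least-squares exponential fit to a pre-binned dwell histogram
#'
#' Fits `A * exp(-t / tau)` to `(mids, counts)` by Levenberg-Marquardt least
#' squares. Exposed so histograms produced elsewhere (or exact noiseless
#' curves) can be fitted directly.
#'
#' @param mids Bin midpoints (s).
#' @param counts Bin counts.
#' @return List with `tau`, `se`, `amplitude`.
#' @export
fit_dwell_histogram <- function(mids, counts) {
  keep <- is.finite(mids) & is.finite(counts)
  mids <- mids[keep]; counts <- counts[keep]
  if (length(mids) < 3) stopf("histogram fit needs >= 3 bins")
  pos <- counts > 0
  tau0 <- if (sum(pos) >= 2) {
    unname(-1 / coef(stats::lm(log(counts[pos]) ~ mids[pos]))[2])
  } else mean(mids)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- mean(mids)
  fit <- minpack.lm::nlsLM(counts ~ A * exp(-mids / tau),
                           start = list(A = max(counts), tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["tau"]], error = function(e) NA_real_)
  list(tau = est[["tau"]], se = se, amplitude = est[["A"]])
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit%s> tau = %.3g +/- %.2g s (%s, n = %d)\n",
              if (!is.null(x$state)) sprintf(" state %s", x$state) else "",
              x$tau, x$se, x$method, x$n))
  invisible(x)
}

#' Transition counts and relative frequencies from decoded paths
#'
#' Counts every i -> j step across all traces, the relative frequency of
#' each transition among all transitions, and the total time spent per state.
#'
#' @param paths A `state_path` or list of them (or integer vectors).
#' @param n_states Number of states (inferred when missing).
#' @param frame_period Frame period in seconds for time-in-state (taken from
#'   path attributes when present).
#' @return An object of class `transition_stats`: matrices `counts` and
#'   `freq` (zero diagonal), vector `time_in_state` (s).
#' @export
transition_frequencies <- function(paths, n_states = NULL, frame_period = NULL) {
  if (!is.list(paths)) paths <- list(paths)
  K <- n_states %||% max(1L, suppressWarnings(max(unlist(lapply(paths, max)),
                                                 na.rm = TRUE)))
  if (!is.finite(K) || K < 1) K <- 1L
  counts <- matrix(0L, K, K)
  tis <- numeric(K)
  for (p in paths) {
    fp <- frame_period %||% attr(p, "frame_period") %||% NA_real_
    v <- as.integer(p)
    if (length(v) == 0) next
    if (!is.na(fp))
      for (k in seq_len(K)) tis[k] <- tis[k] + sum(v == k) * fp
    if (length(v) > 1) {
      from <- v[-length(v)]; to <- v[-1]
      ch <- from != to
      if (any(ch))
        for (i in which(ch)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts * 0
  structure(list(counts = counts, freq = freq, time_in_state = tis,
                 n_transitions = total), class = "transition_stats")
}

#' Derive transition rates from dwell fits and transition counts
#'
#' Under the declared topology, the rate of each allowed transition is the
#' branching fraction times the state's exit rate:
#' `k_ij = (n_ij / sum_j n_ij) / tau_i`, branching restricted to allowed
#' transitions. For a single-exit state this reduces to `k = 1 / tau`.
#' Transitions forbidden by the topology that nevertheless carry more than
#' `forbidden_tol` of all counts trigger a warning (such events arise from
#' the camera's limited temporal resolution).
#'
#' @param dwell_fits Numeric vector of per-state mean dwell times tau (s),
#'   or a list of `dwell_fit` objects ordered by state.
#' @param transition_stats A [transition_frequencies()] result (optional for
#'   topologies where every state has a single exit).
#' @param topology `"two-state"` or `"linear-three-state"`.
#' @param forbidden_tol Warning threshold on the forbidden-count fraction.
#' @return An object of class `rate_matrix`: matrix `k` (1/s, `NA` where
#'   forbidden), `k_rounded` (1 decimal, the reporting precision), `tau`.
#' @examples
#' derive_rates(c(0.24, 0.31, 0.44), topology = "linear-three-state")$k_rounded
#' @export
derive_rates <- function(dwell_fits, transition_stats = NULL,
                         topology = c("two-state", "linear-three-state"),
                         forbidden_tol = 0.05) {
  topology <- match.arg(topology)
  tau <- if (is.list(dwell_fits) && !is.data.frame(dwell_fits)) {
    vapply(dwell_fits, function(f) f$tau, numeric(1))
  } else as.numeric(dwell_fits)
  K <- if (topology == "two-state") 2L else 3L
  if (length(tau) != K)
    stopf("topology %s needs %d dwell times, got %d", topology, K, length(tau))
  if (any(!is.finite(tau) | tau <= 0)) stopf("all dwell times must be > 0")

  allowed <- matrix(FALSE, K, K)
  if (K == 2L) { allowed[1, 2] <- allowed[2, 1] <- TRUE }
  else { allowed[1, 2] <- allowed[2, 1] <- allowed[2, 3] <- allowed[3, 2] <- TRUE }

  counts <- if (!is.null(transition_stats)) transition_stats$counts else NULL
  if (!is.null(counts)) {
    forb <- sum(counts[!allowed & row(counts) != col(counts)])
    if (sum(counts) > 0 && forb / sum(counts) > forbidden_tol)
      warnf("%.1f%% of transitions are forbidden by the %s topology",
            100 * forb / sum(counts), topology)
  }

  k <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    targets <- which(allowed[i, ])
    if (length(targets) == 1L) {
      k[i, targets] <- 1 / tau[i]
    } else {
      if (is.null(counts)) {
        # branching unknown without transition counts; single-exit rates are
        # still exact, so leave the split exits undetermined
        k[i, targets] <- NA_real_
        next
      }
      n_exit <- counts[i, targets]
      if (sum(n_exit) == 0) stopf("no observed exits from state %d", i)
      k[i, targets] <- (n_exit / sum(n_exit)) / tau[i]
    }
  }
  structure(list(k = k, k_rounded = round(k, 1), tau = tau,
                 topology = topology), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %s (1/s, 1 dp)\n", x$topology))
  print(x$k_rounded)
  invisible(x)
}

#' Temperature reduction factor of a dwell time
#'
#' Ratio of the low-temperature to the high-temperature mean dwell time,
#' reported alongside its nearest-integer value (the reporting precision for
#' such factors).
#'
#' @param tau_low_T,tau_high_T Mean dwell times (s) at the two temperatures.
#' @return List with `ratio` and `approx` (nearest integer).
#' @examples
#' temperature_factor(19.2, 1.14)  # ~17
#' @export
temperature_factor <- function(tau_low_T, tau_high_T) {
  if (tau_low_T <= 0 || tau_high_T <= 0) stopf("dwell times must be > 0")
  r <- tau_low_T / tau_high_T
  list(ratio = r, approx = round(r))
}

#' Mono-exponential fit of a complex-survival series
#'
#' Least-squares fit of `f(t) = A * exp(-t / lifetime)` to a surviving
#' fraction series, with the amplitude fixed at 1 by default (all complexes
#' present at t = 0).
#'
#' @param time Sample times (s), or a `survival_series` data.frame from
#'   [simulate_survival()] (then `fraction` is taken from it).
#' @param fraction Surviving fractions at `time`.
#' @param fix_amplitude Fix `A = 1` (default) or fit it.
#' @return An object of class `survival_fit`: `lifetime_s`, `lifetime_min`,
#'   `se_s`, `se_min`, `amplitude`.
#' @export
fit_survival <- function(time, fraction = NULL, fix_amplitude = TRUE) {
  if (is.data.frame(time)) { fraction <- time$fraction; time <- time$time_s }
  if (length(time) < 4) stopf("survival fit needs >= 4 time points")
  if (length(time) != length(fraction)) stopf("time/fraction length mismatch")
  if (all(diff(fraction[order(time)]) >= 0))
    stopf("survival series is non-decreasing; nothing decays")

  pos <- fraction > 0
  tau0 <- if (sum(pos) >= 2) {
    unname(-1 / coef(stats::lm(log(fraction[pos]) ~ time[pos]))[2])
  } else max(time) / 2
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(time) / 2
  if (fix_amplitude) {
    fit <- minpack.lm::nlsLM(fraction ~ exp(-time / tau),
                             start = list(tau = tau0))
    A <- 1
  } else {
    fit <- minpack.lm::nlsLM(fraction ~ A * exp(-time / tau),
                             start = list(A = 1, tau = tau0))
    A <- coef(fit)[["A"]]
  }
  tau <- coef(fit)[["tau"]]
  se <- tryCatch(sqrt(diag(vcov(fit)))[["tau"]], error = function(e) NA_real_)
  structure(list(lifetime_s = tau, lifetime_min = tau / 60,
                 se_s = se, se_min = se / 60, amplitude = A),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> lifetime = %.3g s = %.3g min (+/- %.2g min)\n",
              x$lifetime_s, x$lifetime_min, x$se_min))
  invisible(x)
}

#' Binding-isotherm fit of a bent-fraction titration
#'
#' Weighted least-squares fit of the pseudo-first-order Langmuir isotherm
#' `f(c) = c / (c + Kd)` (protein in large excess over DNA, so free protein
#' equals total protein). When per-point trial counts are available the
#' points are weighted by the inverse binomial variance.
#'
#' @param concentration Protein concentrations (nM), or a `titration_curve`
#'   data.frame from [simulate_titration()].
#' @param fraction Bent fractions at each concentration.
#' @param n_per_point Trials per point for binomial weighting (optional).
#' @return An object of class `kd_fit`: `kd` (nM), `se`.
#' @export
fit_kd <- function(concentration, fraction = NULL, n_per_point = NULL) {
  if (is.data.frame(concentration)) {
    n_per_point <- n_per_point %||% concentration$n
    fraction <- concentration$fraction
    concentration <- concentration$concentration_nM
  }
  if (length(concentration) < 4)
    stopf("Kd fit needs >= 4 concentrations spanning the transition")
  if (all(fraction <= 0) || all(fraction >= 1))
    stopf("titration is unidentifiable: all fractions are %s",
          if (all(fraction <= 0)) "zero" else "one")

  w <- rep(1, length(fraction))
  if (!is.null(n_per_point)) {
    v <- fraction * (1 - fraction) / n_per_point
    v[v <= 0] <- min(v[v > 0], 1e-6)
    w <- 1 / v
  }
  mid <- stats::approx(fraction, concentration, xout = 0.5, ties = mean)$y
  kd0 <- if (is.finite(mid) && mid > 0) mid else median(concentration)
  fit <- minpack.lm::nlsLM(fraction ~ concentration / (concentration + kd),
                           start = list(kd = kd0), weights = w,
                           lower = 1e-9)
  kd <- coef(fit)[["kd"]]
  se <- tryCatch(sqrt(diag(vcov(fit)))[["kd"]], error = function(e) NA_real_)
  structure(list(kd = kd, se = se), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd = %.3g +/- %.2g nM\n", x$kd, x$se))
  invisible(x)
}
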