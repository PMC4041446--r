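#' Background and crosstalk correction of a TIRF trace
#'
#' Subtracts per-channel background (scalars or per-frame series), removes
#' donor leakage and direct acceptor excitation from the acceptor channel
#' (`I_A <- I_A - leakage * I_D - direct_exc * a_ref`), and computes the
#' per-frame proximity ratio `E = I_A / (I_A + I_D)`. Frames with
#' non-positive total intensity get `E = NA` (masked).
#'
#' @param trace A `fret_trace` data.frame with `I_D`, `I_A`.
#' @param background Length-2 vector `c(D, A)` of scalar backgrounds, or a
#'   two-column matrix/data.frame of per-frame background series.
#' @param corrections A [correction_factors()].
#' @param a_ref Reference acceptor intensity for the direct-excitation term
#'   (e.g. the mean acceptor-excitation intensity); default 0.
#' @return The trace with corrected intensities and an `E` column.
#' @export
correct_trace <- function(trace, background = c(0, 0),
                          corrections = correction_factors(), a_ref = 0) {
  n <- nrow(trace)
  if (is.matrix(background) || is.data.frame(background)) {
    if (nrow(background) != n)
      stopf("background series length %d does not match trace length %d",
            nrow(background), n)
    bg_d <- background[[1]]; bg_a <- background[[2]]
  } else {
    if (length(background) != 2)
      stopf("background must be c(D, A) or a per-frame two-column series")
    bg_d <- background[1]; bg_a <- background[2]
  }
  I_D <- trace$I_D - bg_d
  I_A <- trace$I_A - bg_a - corrections$leakage * I_D -
    corrections$direct_exc * a_ref
  tot <- I_D + I_A
  trace$I_D <- I_D
  trace$I_A <- I_A
  trace$E <- ifelse(tot > 0, I_A / tot, NA_real_)
  attr(trace, "corrected") <- TRUE
  trace
}

#' Detect single-step photobleaching and truncate the analysable range
#'
#' Scans the total intensity `I_D + I_A` for the first single-step drop below
#' `frac` times its preceding running median; the step frame is refined to
#' the largest one-frame drop near the candidate. Traces without a detected
#' step keep their full range.
#'
#' @param trace A (corrected) `fret_trace`.
#' @param frac Drop threshold as a fraction of the preceding running median.
#' @param window Running-median window in frames (odd).
#' @return Integer `c(first, last)` analysable frame; also stored on the
#'   trace attribute `valid_range` of the returned trace via
#'   `attr(trace, "valid_range")` when assigned by the caller.
#' @export
detect_bleaching <- function(trace, frac = 0.5, window = 15) {
  n <- nrow(trace)
  k <- if (window %% 2 == 1) window else window + 1
  if (n < 2 * k) return(c(1L, n))
  half <- (k - 1) / 2

  # first frame whose forward running median falls below frac times the
  # backward running median, refined to the largest one-frame drop nearby
  find_step <- function(x) {
    med <- runmed(x, k)
    idx <- seq(half + 1, n - half)
    fwd <- med[pmin(idx + half, n)]
    bwd <- med[pmax(idx - half, 1)]
    hit <- which(fwd < frac * bwd & bwd > 0)
    if (!length(hit)) return(NA_integer_)
    cand <- idx[hit[1]]
    lo <- max(2L, cand - k); hi <- min(n, cand + k)
    drops <- diff(x)[(lo - 1):(hi - 1)]
    (lo:hi)[which.min(drops)]        # frame index of the post-drop frame
  }

  step_tot <- find_step(trace$I_D + trace$I_A)
  # acceptor bleach leaves the total constant (donor de-quenches): look for an
  # acceptor-channel step accompanied by a donor rise
  step_acc <- find_step(trace$I_A)
  if (!is.na(step_acc)) {
    pre <- trace$I_D[max(1, step_acc - k):(step_acc - 1)]
    post <- trace$I_D[step_acc:min(n, step_acc + k)]
    if (!(length(pre) && length(post) && median(post) > median(pre)))
      step_acc <- NA_integer_
  }
  step <- suppressWarnings(min(step_tot, step_acc, na.rm = TRUE))
  if (!is.finite(step)) return(c(1L, n))
  c(1L, max(1L, as.integer(step) - 1L))
}

#' Restrict traces to their pre-bleach range
#'
#' Applies [detect_bleaching()] to each trace and truncates it, recording the
#' detected range.
#'
#' @param traces List of corrected `fret_trace` objects.
#' @param ... Passed to [detect_bleaching()].
#' @return List of truncated traces with attribute `valid_range`.
#' @export
truncate_at_bleach <- function(traces, ...) {
  lapply(traces, function(tr) {
    vr <- detect_bleaching(tr, ...)
    out <- tr[vr[1]:vr[2], , drop = FALSE]
    for (a in c("frame_period", "trace_id", "truth", "corrected"))
      attr(out, a) <- attr(tr, a)
    attr(out, "valid_range") <- vr
    class(out) <- class(tr)
    out
  })
}
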