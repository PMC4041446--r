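#' Fit a Gaussian-emission hidden Markov model to FRET traces
#'
#' Maximum-likelihood expectation-maximization (Baum-Welch) over the pooled
#' per-frame proximity ratios of one or more traces, with `K` hidden states,
#' Gaussian emissions and a shared per-frame transition matrix. The HMM
#' operates on the one-dimensional E(t) signal; frames with `NA` E are
#' treated as missing emissions. The number of states is fixed by the user
#' (two for the archaeal systems, three for the eukaryotic TBP/TF(II)B
#' complex); no model selection is performed. Initialization places state
#' means at evenly spaced quantiles of the pooled signal; additional random
#' restarts redraw the means uniformly over the observed range and the best
#' likelihood is kept. States are relabelled in ascending order of mean.
#'
#' @param traces A list of `fret_trace` objects with an `E` column (see
#'   [correct_trace()]), a list of numeric vectors, or a single numeric
#'   vector.
#' @param K Number of hidden states (1-3).
#' @param n_restarts EM restarts (first uses quantile initialization).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param sd_floor Lower bound on emission standard deviations.
#' @param seed RNG seed for the random restarts.
#' @return An object of class `hmm_fit`: `mu`, `sigma`, transition matrix
#'   `A` (per frame), initial distribution `pi`, `loglik`, `loglik_trace`
#'   (per-iteration, non-decreasing), `converged`, `K`.
#' @examples
#' e <- rep(c(0.25, 0.49), each = 50) + rnorm(100, sd = 0.02)
#' fit <- fit_hmm(e, K = 2, n_restarts = 2, seed = 1)
#' fit$mu
#' @export
fit_hmm <- function(traces, K, n_restarts = 10, max_iter = 200, tol = 1e-6,
                    sd_floor = 1e-3, seed = 1L) {
  obs <- as_obs_list(traces)
  pooled <- unlist(obs, use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) < 10)
    stopf("HMM fit needs at least one trace with >= 10 valid frames")
  if (!K %in% 1:3) stopf("K must be 1, 2 or 3")
  if (sd(pooled) < 1e-12)
    stopf("degenerate data: pooled E signal is constant, emissions are not identifiable")

  if (K == 1) {
    mu <- mean(pooled); sig <- max(sd(pooled), sd_floor)
    ll <- sum(dnorm(pooled, mu, sig, log = TRUE))
    return(structure(list(mu = mu, sigma = sig, A = matrix(1, 1, 1),
                          pi = 1, loglik = ll, loglik_trace = ll,
                          converged = TRUE, K = 1L), class = "hmm_fit"))
  }

  run_em <- function(mu0) {
    mu <- sort(mu0)
    sig <- rep(max(sd(pooled), sd_floor), K)
    A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
    pi <- rep(1 / K, K)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      st <- hmm_estep(obs, mu, sig, A, pi)
      ll <- st$loglik
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll < ll_old - 1e-6 * abs(ll_old))
        warnf("EM log-likelihood decreased at iteration %d", it)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      # M-step
      g <- pmax(st$g_obs, 1e-12)
      mu <- st$gx / g
      sig <- pmax(sqrt(pmax(st$gxx / g - mu^2, 0)), sd_floor)
      A <- st$xi / pmax(st$g_trans, 1e-12)
      A <- A / rowSums(A)
      pi <- st$g1 / sum(st$g1)
    }
    list(mu = mu, sigma = sig, A = A, pi = pi, loglik = ll_trace[length(ll_trace)],
         loglik_trace = ll_trace, converged = converged)
  }

  inits <- with_seed(seed, {
    qs <- as.numeric(quantile(pooled, seq_len(K) / (K + 1)))
    more <- lapply(seq_len(max(0, n_restarts - 1)), function(i)
      runif(K, min(pooled), max(pooled)))
    c(list(qs), more)
  })
  best <- NULL
  for (mu0 in inits) {
    res <- run_em(mu0)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }

  # canonical ordering: ascending means
  ord <- order(best$mu)
  fit <- list(mu = best$mu[ord], sigma = best$sigma[ord],
              A = best$A[ord, ord, drop = FALSE], pi = best$pi[ord],
              loglik = best$loglik, loglik_trace = best$loglik_trace,
              converged = best$converged, K = as.integer(K))
  structure(fit, class = "hmm_fit")
}

as_obs_list <- function(traces) {
  if (is.numeric(traces)) return(list(as.numeric(traces)))
  if (is.data.frame(traces)) traces <- list(traces)
  lapply(traces, function(tr) {
    if (is.numeric(tr)) return(as.numeric(tr))
    if (!is.null(tr$E)) return(as.numeric(tr$E))
    stopf("traces must carry an E column (run correct_trace() first) or be numeric")
  })
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d, loglik = %.1f%s\n", x$K, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat("  means: ", paste(sprintf("%.3f", x$mu), collapse = ", "), "\n")
  cat("  sds:   ", paste(sprintf("%.3f", x$sigma), collapse = ", "), "\n")
  invisible(x)
}

#' Viterbi decoding of a trace under a fitted HMM
#'
#' Most probable hidden-state sequence; deterministic, with ties broken
#' toward the lower-index state. `NA` frames are bridged by the transition
#' model (missing emissions).
#'
#' @param model An `hmm_fit`.
#' @param trace A `fret_trace` with an `E` column, or a numeric vector.
#' @return Integer vector of state labels (1..K), one per frame, of class
#'   `state_path`.
#' @export
viterbi_path <- function(model, trace) {
  stopifnot(inherits(model, "hmm_fit"))
  x <- if (is.numeric(trace)) trace else trace$E
  path <- hmm_viterbi(as.numeric(x), model$mu, model$sigma, model$A,
                      model$pi)
  structure(path, class = "state_path",
            frame_period = attr(trace, "frame_period"),
            trace_id = attr(trace, "trace_id"))
}

#' Extract dwell times from decoded state paths
#'
#' Run-length encodes each path into per-state dwells in seconds. The first
#' and last dwell of every trace are truncated by the observation window and
#' flagged censored; exponential fitting excludes them by default.
#'
#' @param paths A `state_path`, or a list of them (or plain integer vectors).
#' @param frame_period Frame period in seconds (taken from the path
#'   attribute when present).
#' @return A data.frame of class `dwell_set`: `trace`, `state`, `n_frames`,
#'   `duration_s`, `censored_left`, `censored_right`, `censored`.
#' @examples
#' extract_dwells(list(c(1, 1, 2, 2, 2, 1)), frame_period = 0.05)
#' @export
extract_dwells <- function(paths, frame_period = NULL) {
  if (!is.list(paths)) paths <- list(paths)
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    fp <- frame_period %||% attr(p, "frame_period")
    if (is.null(fp)) stopf("frame_period is required")
    id <- attr(p, "trace_id") %||% sprintf("trace%04d", i)
    r <- rle(as.integer(p))
    n <- length(r$lengths)
    data.frame(trace = id, state = r$values, n_frames = r$lengths,
               duration_s = r$lengths * fp,
               censored_left = seq_len(n) == 1L,
               censored_right = seq_len(n) == n)
  })
  d <- do.call(rbind, out)
  d$censored <- d$censored_left | d$censored_right
  structure(d, class = c("dwell_set", "data.frame"))
}
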