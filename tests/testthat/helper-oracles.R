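# Independent brute-force oracles the fast implementations are tested against.

# O(n^2) sliding-window burst search: a photon qualifies iff >= M photons lie
# within the length-T window centered on it; bursts are maximal runs of >= N
# consecutive qualifying photons.
brute_force_bursts <- function(ts, T_us, M, N, anchor = "center") {
  n <- length(ts)
  if (n == 0) return(data.frame(i_start = integer(0), i_stop = integer(0)))
  qual <- vapply(seq_len(n), function(i) {
    if (anchor == "center") sum(abs(ts - ts[i]) <= T_us / 2) >= M
    else sum(ts >= ts[i] & ts < ts[i] + T_us) >= M
  }, logical(1))
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= N
  data.frame(i_start = starts[keep], i_stop = ends[keep])
}

# double-loop exponential kernel sum
brute_kde <- function(eval, src, tau) {
  vapply(eval, function(e) sum(exp(-abs(e - src) / tau)), numeric(1))
}

# ALEX-2CDE / FRET-2CDE evaluated straight from the kernel formulas
brute_two_cde <- function(t_all, cls, tau = 100) {
  t_dex <- t_all[cls %in% c("DD", "AD")]
  t_aex <- t_all[cls %in% c("AA", "DA")]
  t_dd <- t_all[cls == "DD"]; t_ad <- t_all[cls == "AD"]
  alex <- NA_real_
  if (length(t_dex) && length(t_aex)) {
    br_da <- sum(brute_kde(t_aex, t_dex, tau) / brute_kde(t_aex, t_aex, tau)) /
      length(t_dex)
    br_ad <- sum(brute_kde(t_dex, t_aex, tau) / brute_kde(t_dex, t_dex, tau)) /
      length(t_aex)
    alex <- 100 - 50 * (br_da + br_ad)
  }
  fret <- NA_real_
  if (length(t_dd) > 1 && length(t_ad) > 1) {
    nb <- function(te, N) (1 + 2 / N) * (brute_kde(te, te, tau) - 1)
    e_d <- mean(brute_kde(t_dd, t_ad, tau) /
                  (brute_kde(t_dd, t_ad, tau) + nb(t_dd, length(t_dd))))
    e_a <- mean(brute_kde(t_ad, t_dd, tau) /
                  (brute_kde(t_ad, t_dd, tau) + nb(t_ad, length(t_ad))))
    fret <- 110 - 100 * (e_d + e_a)
  }
  c(alex = alex, fret = fret)
}

# exhaustive Viterbi: enumerate all K^T state paths, return the most probable
enum_viterbi <- function(x, mu, sigma, A, pi) {
  K <- length(mu); T_len <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(grid, 1, function(s) {
    v <- log(pi[s[1]])
    if (T_len > 1)
      v <- v + sum(log(A[cbind(s[-T_len], s[-1])]))
    obs <- !is.na(x)
    v + sum(dnorm(x[obs], mu[s[obs]], sigma[s[obs]], log = TRUE))
  })
  as.integer(grid[which.max(lp), ])
}

# ground-truth species of each detected burst, from the generator's truth
# table (matched by burst midpoint; "background" if no envelope overlaps)
burst_species <- function(bursts, stream) {
  truth <- attr(stream, "truth")
  mid <- (bursts$start_us + bursts$stop_us) / 2
  vapply(mid, function(m) {
    hit <- which(truth$start_us <= m & truth$stop_us >= m)
    if (length(hit)) truth$species[hit[1]] else "background"
  }, character(1))
}

# assemble a photon_stream object from raw vectors (test fixtures)
make_stream <- function(ts, channel, period = 100, duty = 0.5,
                        duration = max(ts) * 1e-6) {
  s <- data.frame(timestamp_us = as.numeric(ts), channel = channel,
                  stringsAsFactors = FALSE)
  attr(s, "alternation_period") <- period
  attr(s, "duty") <- duty
  attr(s, "duration") <- duration
  classify_photons(s)
}

# constant-rate interleaved dual-labelled burst: DD/AD at ratio (1-E):E in
# donor gates, AA in acceptor gates
make_static_burst_stream <- function(n_periods = 60, per_gate = 3, E = 0.4,
                                     period = 100) {
  ts <- c(); ch <- c()
  for (p in seq_len(n_periods)) {
    base <- (p - 1) * period
    td <- base + sort(sample(0:49, per_gate))
    ta <- base + sort(sample(50:99, per_gate))
    ts <- c(ts, td, ta)
    ch <- c(ch, ifelse(runif(per_gate) < E, "acceptor", "donor"),
            rep("acceptor", per_gate))
  }
  make_stream(ts, ch, period = period)
}
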