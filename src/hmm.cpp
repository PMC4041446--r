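#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass over a list of observation vectors sharing one
// Gaussian-emission HMM. NA observations are missing emissions: every state
// gets likelihood 1 at that frame and the frame is excluded from the emission
// sufficient statistics. Returns the total log-likelihood plus the pooled
// statistics the M-step needs.
// [[Rcpp::export]]
List hmm_estep(List obs, NumericVector mu, NumericVector sigma,
               NumericMatrix A, NumericVector pi) {
  const int K = mu.size();
  double loglik = 0.0;
  NumericVector g_obs(K);   // sum of gamma over frames with an observation
  NumericVector gx(K);      // sum gamma * x
  NumericVector gxx(K);     // sum gamma * x^2
  NumericVector g1(K);      // gamma at t = 1, summed over traces
  NumericVector g_trans(K); // sum of gamma over t = 1..T-1 (xi row totals)
  NumericMatrix xi(K, K);   // expected transition counts

  for (int tr = 0; tr < obs.size(); ++tr) {
    NumericVector x = obs[tr];
    const int T = x.size();
    if (T == 0) continue;

    NumericMatrix B(T, K);
    for (int t = 0; t < T; ++t) {
      const bool miss = NumericVector::is_na(x[t]);
      for (int k = 0; k < K; ++k)
        B(t, k) = miss ? 1.0 : R::dnorm(x[t], mu[k], sigma[k], 0);
    }

    NumericMatrix alpha(T, K), beta(T, K);
    std::vector<double> c(T);

    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
    if (s <= 0.0) s = 1e-300;
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;

    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        a *= B(t, k);
        alpha(t, k) = a;
        s += a;
      }
      if (s <= 0.0) s = 1e-300;
      c[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double b = 0.0;
        for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = b / c[t + 1];
      }
    }

    for (int t = 0; t < T; ++t) {
      double norm = 0.0;
      std::vector<double> g(K);
      for (int k = 0; k < K; ++k) { g[k] = alpha(t, k) * beta(t, k); norm += g[k]; }
      if (norm <= 0.0) norm = 1e-300;
      const bool miss = NumericVector::is_na(x[t]);
      for (int k = 0; k < K; ++k) {
        const double gk = g[k] / norm;
        if (!miss) {
          g_obs[k] += gk;
          gx[k] += gk * x[t];
          gxx[k] += gk * x[t] * x[t];
        }
        if (t == 0) g1[k] += gk;
        if (t < T - 1) g_trans[k] += gk;
      }
      if (t < T - 1) {
        for (int j = 0; j < K; ++j)
          for (int k = 0; k < K; ++k)
            xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["g_obs"] = g_obs, _["gx"] = gx,
                      _["gxx"] = gxx, _["g1"] = g1, _["g_trans"] = g_trans,
                      _["xi"] = xi);
}

// Viterbi decoding in log space. Ties are broken toward the lower state index
// (strict inequality while scanning states in ascending order). NA frames are
// missing emissions and contribute no emission term.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericMatrix A, NumericVector pi) {
  const int K = mu.size();
  const int T = x.size();
  IntegerVector path(T);
  if (T == 0) return path;

  const double NEG = -1e300;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  auto logB = [&](int t, int k) -> double {
    if (NumericVector::is_na(x[t])) return 0.0;
    return R::dnorm(x[t], mu[k], sigma[k], 1);
  };

  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0.0 ? std::log(pi[k]) : NEG) + logB(0, k);

  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG * 2;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double la = (A(j, k) > 0.0 ? std::log(A(j, k)) : NEG);
        const double cand = delta(t - 1, j) + la;
        if (cand > best) { best = cand; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }

  double best = NEG * 2;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
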