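#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exponential-kernel density sums: for each evaluation time e_i returns
//   sum_j exp(-|e_i - t_j| / tau)
// over source times t_j. Both vectors must be sorted ascending. Linear-time
// left/right recursions replace the naive O(n*m) double loop.
// [[Rcpp::export]]
NumericVector exp_kde(NumericVector eval, NumericVector src, double tau) {
  const int n = eval.size(), m = src.size();
  NumericVector out(n);
  if (m == 0 || n == 0) return out;

  // left: contributions from src <= eval[i]
  double acc = 0.0;
  int j = 0;
  double prev = eval.size() > 0 ? eval[0] : 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) acc *= std::exp(-(eval[i] - prev) / tau);
    while (j < m && src[j] <= eval[i]) {
      acc += std::exp(-(eval[i] - src[j]) / tau);
      ++j;
    }
    out[i] = acc;
    prev = eval[i];
  }
  // right: contributions from src > eval[i]
  acc = 0.0;
  j = m - 1;
  prev = eval[n - 1];
  for (int i = n - 1; i >= 0; --i) {
    if (i < n - 1) acc *= std::exp(-(prev - eval[i]) / tau);
    while (j >= 0 && src[j] > eval[i]) {
      acc += std::exp(-(src[j] - eval[i]) / tau);
      --j;
    }
    out[i] += acc;
    prev = eval[i];
  }
  return out;
}

// Force a sorted numeric timestamp vector to be strictly increasing by
// bumping collided values up by one clock unit.
// [[Rcpp::export]]
NumericVector make_strict_increasing(NumericVector t) {
  const int n = t.size();
  NumericVector out = clone(t);
  for (int i = 1; i < n; ++i)
    if (out[i] <= out[i - 1]) out[i] = out[i - 1] + 1.0;
  return out;
}
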