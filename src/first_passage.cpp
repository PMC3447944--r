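#include <Rcpp.h>
using namespace Rcpp;

// First-passage mass function by iterated vector-matrix products.
// P must have an absorbing terminal state (row `to` = unit vector); the
// cumulative arrival probability after k steps is then (P^k)[from, to].
// Returns f (length k_max) with f[k] = F(k) - F(k-1), plus the tail mass.
// [[Rcpp::export]]
List fp_law_dense(NumericMatrix P, int k_max, int from = 1, int to = -1) {
  int n = P.nrow();
  if (to < 0) to = n;
  std::vector<double> v(n, 0.0), w(n, 0.0);
  v[from - 1] = 1.0;
  NumericVector f(k_max);
  double prev = 0.0;
  for (int k = 0; k < k_max; ++k) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[i] * P(i, j);
      w[j] = s;
    }
    std::swap(v, w);
    double cum = v[to - 1];
    f[k] = cum - prev;
    prev = cum;
  }
  return List::create(_["f"] = f, _["tail_mass"] = 1.0 - prev);
}

// Same law for the canonical birth-death chain used throughout: vertex 1
// reflecting (backward folds into staying), vertex n absorbing. O(n) per
// step; used inside grid searches where the dense version would be wasteful.
// States are 0-indexed here; absorbing state is a = n - 1.
// [[Rcpp::export]]
List fp_law_tridiag(double q_fwd, double q_bwd, double q_stay,
                    int n, int k_max) {
  int a = n - 1;
  std::vector<double> v(n, 0.0), w(n, 0.0);
  v[0] = 1.0;
  NumericVector f(k_max);
  double prev = 0.0;
  for (int k = 0; k < k_max; ++k) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      if (j == a) {
        s = v[a];                                // absorbed mass stays
        if (a >= 1) s += v[a - 1] * q_fwd;       // new arrivals
      } else {
        if (j == 0) s += v[0] * (q_stay + q_bwd);  // reflecting boundary
        else s += v[j] * q_stay + v[j - 1] * q_fwd;
        if (j + 1 <= a - 1) s += v[j + 1] * q_bwd; // never from absorber
      }
      w[j] = s;
    }
    std::swap(v, w);
    double cum = v[a];
    f[k] = cum - prev;
    prev = cum;
    if (1.0 - prev < 1e-15) break;  // fully absorbed; rest of f is zero
  }
  return List::create(_["f"] = f, _["tail_mass"] = 1.0 - prev);
}
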