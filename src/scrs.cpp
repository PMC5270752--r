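#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Asymmetric least squares baseline (Eilers-style): minimise
//   sum_i w_i (y_i - b_i)^2 + lam * sum (d2 b)^2,  w_i = p if y_i > b_i else 1-p.
// The normal matrix W + lam * D2'D2 is symmetric pentadiagonal; solved by a
// banded Cholesky each reweighting pass.
// [[Rcpp::export]]
NumericVector als_baseline_cpp(NumericVector y, double lam, double p, int n_iter) {
  const int n = y.size();
  if (n < 3) stop("need at least 3 points for a second-difference penalty");
  std::vector<double> d0(n, 0.0), d1(n - 1, 0.0), d2(n - 2, 0.0);
  for (int k = 0; k <= n - 3; ++k) {
    d0[k]     += lam * 1.0;
    d0[k + 1] += lam * 4.0;
    d0[k + 2] += lam * 1.0;
    d1[k]     += lam * -2.0;
    d1[k + 1] += lam * -2.0;
    d2[k]     += lam * 1.0;
  }
  std::vector<double> w(n, 1.0), b(n, 0.0);
  std::vector<double> l0(n), l1(n, 0.0), l2(n, 0.0), z(n);
  for (int iter = 0; iter < n_iter; ++iter) {
    // banded Cholesky of A = diag(w) + lam D2'D2 (bandwidth 2)
    for (int i = 0; i < n; ++i) {
      double a0 = d0[i] + w[i];
      double li2 = 0.0, li1 = 0.0;
      if (i >= 2) li2 = d2[i - 2] / l0[i - 2];
      if (i >= 1) {
        double a1 = d1[i - 1];
        if (i >= 2) a1 -= li2 * l1[i - 1] * 1.0; // L[i][i-2]*L[i-1][i-2]
        li1 = a1 / l0[i - 1];
      }
      l2[i] = li2;
      l1[i] = li1;
      double diag = a0 - li1 * li1 - li2 * li2;
      if (diag <= 0) stop("baseline system not positive definite");
      l0[i] = std::sqrt(diag);
    }
    // forward solve L z = w*y
    for (int i = 0; i < n; ++i) {
      double rhs = w[i] * y[i];
      if (i >= 1) rhs -= l1[i] * z[i - 1];
      if (i >= 2) rhs -= l2[i] * z[i - 2];
      z[i] = rhs / l0[i];
    }
    // back solve L' b = z
    for (int i = n - 1; i >= 0; --i) {
      double rhs = z[i];
      if (i + 1 < n) rhs -= l1[i + 1] * b[i + 1];
      if (i + 2 < n) rhs -= l2[i + 2] * b[i + 2];
      b[i] = rhs / l0[i];
    }
    for (int i = 0; i < n; ++i) w[i] = (y[i] > b[i]) ? p : 1.0 - p;
  }
  return NumericVector(b.begin(), b.end());
}

// All strict local maxima of y with their prominences. A peak's bases are the
// minima between the peak and the nearest strictly higher sample on each side
// (or the signal edge); prominence = height - max(left base, right base).
// Returns 1-based indices.
// [[Rcpp::export]]
List find_peaks_cpp(NumericVector y) {
  const int n = y.size();
  std::vector<int> idx;
  std::vector<double> height, prom;
  for (int i = 1; i + 1 < n; ++i) {
    if (!(y[i] > y[i - 1] && y[i] > y[i + 1])) continue;
    double lbase = y[i], rbase = y[i];
    for (int j = i - 1; j >= 0; --j) {
      if (y[j] > y[i]) break;
      if (y[j] < lbase) lbase = y[j];
    }
    for (int j = i + 1; j < n; ++j) {
      if (y[j] > y[i]) break;
      if (y[j] < rbase) rbase = y[j];
    }
    idx.push_back(i + 1);
    height.push_back(y[i]);
    prom.push_back(y[i] - std::max(lbase, rbase));
  }
  return List::create(_["index"] = IntegerVector(idx.begin(), idx.end()),
                      _["height"] = NumericVector(height.begin(), height.end()),
                      _["prominence"] = NumericVector(prom.begin(), prom.end()));
}
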