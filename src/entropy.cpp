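#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Chebyshev distance between the length-m templates starting at i and j.
static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(x[i + k] - x[j + k]);
    if (v > d) d = v;
  }
  return d;
}

// Approximate entropy with self-match inclusion: counts S_i >= 1 so the log
// is always defined. phi^m averages ln(S_i / n) over the n = L - m + 1
// templates of length m; AE = phi^m - phi^{m+1}.
// strict = true drops the self-match from the count (for study only; S_i can
// then be 0, in which case the template contributes ln of the smallest
// positive count ratio is undefined -> returns NA).
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r, bool strict = false) {
  int L = x.size();
  const double* px = REAL(x);
  double phi[2];
  for (int q = 0; q < 2; ++q) {
    int mm = m + q;
    int n = L - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        if (strict && j == i) continue;
        if (cheb(px, i, j, mm) <= r) ++cnt;
      }
      if (cnt == 0) return NA_REAL;
      acc += std::log((double)cnt / (double)n);
    }
    phi[q] = acc / (double)n;
  }
  return phi[0] - phi[1];
}

// Sample entropy (Richman & Moorman): n = L - m templates at both orders,
// self-matches excluded. SE = ln(B / A) where B and A are the total match
// counts at order m and m + 1. A == 0 -> NA (undefined-entropy sentinel).
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int L = x.size();
  const double* px = REAL(x);
  int n = L - m;
  double B = 0.0, A = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (cheb(px, i, j, m) <= r) {
        B += 1.0;
        if (std::fabs(px[i + m] - px[j + m]) <= r) A += 1.0;
      }
    }
  }
  if (A <= 0.0) return NA_REAL;
  return std::log(B / A);
}

// Fuzzy entropy: templates are baseline-centered by their own mean, the hard
// match indicator is replaced by exp(-d^nexp / r), and the double average
// runs over the n = L - m templates at both orders (j != i).
// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, double nexp, double r) {
  int L = x.size();
  const double* px = REAL(x);
  int n = L - m;
  double gm[2];
  for (int q = 0; q < 2; ++q) {
    int mm = m + q;
    std::vector<double> c((size_t)n * mm);
    for (int i = 0; i < n; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += px[i + k];
      mu /= (double)mm;
      for (int k = 0; k < mm; ++k) c[(size_t)i * mm + k] = px[i + k] - mu;
    }
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double si = 0.0;
      const double* ci = &c[(size_t)i * mm];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double* cj = &c[(size_t)j * mm];
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double v = std::fabs(ci[k] - cj[k]);
          if (v > d) d = v;
        }
        si += std::exp(-std::pow(d, nexp) / r);
      }
      acc += si / (double)(n - 1);
    }
    gm[q] = acc / (double)n;
  }
  return std::log(gm[0]) - std::log(gm[1]);
}
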