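#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy binary classification tree on weighted samples.
// Splits minimise the weighted Gini impurity sum(W_child * gini_child);
// candidate thresholds are midpoints between consecutive distinct sorted
// feature values. Ties broken by the smallest threshold, then the lowest
// feature index. Leaves predict the sign of the weighted class majority
// (ties -> +1). Labels must be in {-1, +1}.

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth;
  std::vector<int> feature, left, right;
  std::vector<double> threshold, pred;
  int depth_reached;

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const NumericVector& w_, int md)
    : X(X_), y(y_), w(w_), max_depth(md), depth_reached(0) {}

  int new_node() {
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1); pred.push_back(0.0);
    return (int)feature.size() - 1;
  }

  static double gini(double wp, double wn) {
    double wt = wp + wn;
    if (wt <= 0.0) return 0.0;
    double pp = wp / wt, pn = wn / wt;
    return 1.0 - pp * pp - pn * pn;
  }

  int build(std::vector<int>& idx, int depth) {
    int node = new_node();
    if (depth > depth_reached) depth_reached = depth;
    double wp = 0.0, wn = 0.0;
    for (int i : idx) (y[i] > 0 ? wp : wn) += w[i];
    pred[node] = (wp >= wn) ? 1.0 : -1.0;
    bool pure = (wp <= 0.0) || (wn <= 0.0);
    if (depth >= max_depth || pure || idx.size() < 2) return node;

    const double eps = 1e-12;
    double best_imp = R_PosInf, best_thr = 0.0;
    int best_f = -1;
    int p = X.ncol();
    std::vector<int> ord(idx);
    for (int f = 0; f < p; ++f) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double lwp = 0.0, lwn = 0.0;
      for (size_t k = 0; k + 1 < ord.size(); ++k) {
        int i = ord[k];
        (y[i] > 0 ? lwp : lwn) += w[i];
        double v0 = X(i, f), v1 = X(ord[k + 1], f);
        if (v1 <= v0) continue;  // not a boundary between distinct values
        double thr = 0.5 * (v0 + v1);
        double imp = (lwp + lwn) * gini(lwp, lwn) +
                     (wp - lwp + wn - lwn) * gini(wp - lwp, wn - lwn);
        bool better = imp < best_imp - eps;
        bool tie = std::fabs(imp - best_imp) <= eps;
        if (better ||
            (tie && (thr < best_thr - eps ||
                     (std::fabs(thr - best_thr) <= eps && f < best_f)))) {
          best_imp = imp; best_thr = thr; best_f = f;
        }
      }
    }
    if (best_f < 0) return node;  // all feature values identical

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    feature[node] = best_f;
    threshold[node] = best_thr;
    left[node] = build(li, depth + 1);
    right[node] = build(ri, depth + 1);
    return node;
  }
};

// [[Rcpp::export]]
List tree_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth) {
  Builder b(X, y, w, max_depth);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.build(idx, 0);
  return List::create(
    _["feature"] = wrap(b.feature),
    _["threshold"] = wrap(b.threshold),
    _["left"] = wrap(b.left),
    _["right"] = wrap(b.right),
    _["pred"] = wrap(b.pred),
    _["depth"] = b.depth_reached);
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector pred, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
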