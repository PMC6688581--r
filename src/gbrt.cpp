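// Gradient boosted regression tree core.
//
// Stagewise additive model F_m(x) = F_{m-1}(x) + nu * beta_m * h_m(x) with
// half-squared-error loss, CART-style least-squares trees of fixed depth,
// leaf values equal to the mean pseudo-residual in the leaf, and a closed-form
// line search for beta_m.  Everything is deterministic: split thresholds sit
// at midpoints between consecutive distinct sorted feature values, and ties
// in split SSE are broken by lowest feature index, then lowest threshold.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat;      // -1 => leaf
  double thr;
  double value;  // mean of targets reaching this node
  int left;
  int right;
};

// Best split over all (feature, midpoint-threshold) candidates for the rows
// in idx; returns false when no admissible split exists.  Ties broken by the
// scan order: features ascending, thresholds ascending within a feature.
bool find_best_split(const NumericMatrix& X, const std::vector<double>& y,
                     const std::vector<int>& idx, int min_leaf,
                     int& best_feat, double& best_thr, double& best_sse) {
  const int m = (int)idx.size(), p = X.ncol();
  bool found = false;
  std::vector<std::pair<double, double>> v(m);
  for (int j = 0; j < p; ++j) {
    for (int k = 0; k < m; ++k) v[k] = std::make_pair(X(idx[k], j), y[idx[k]]);
    std::stable_sort(v.begin(), v.end(),
                     [](const std::pair<double, double>& a,
                        const std::pair<double, double>& b) { return a.first < b.first; });
    double sumT = 0.0, sqT = 0.0;
    for (int k = 0; k < m; ++k) { sumT += v[k].second; sqT += v[k].second * v[k].second; }
    double sumL = 0.0, sqL = 0.0;
    for (int k = 1; k < m; ++k) {
      sumL += v[k - 1].second;
      sqL += v[k - 1].second * v[k - 1].second;
      if (!(v[k].first > v[k - 1].first)) continue;  // need distinct values
      if (k < min_leaf || m - k < min_leaf) continue;
      const double sumR = sumT - sumL, sqR = sqT - sqL;
      const double sse = (sqL - sumL * sumL / k) + (sqR - sumR * sumR / (m - k));
      if (!found || sse < best_sse) {
        found = true;
        best_sse = sse;
        best_feat = j;
        best_thr = 0.5 * (v[k - 1].first + v[k].first);
      }
    }
  }
  return found;
}

int grow(const NumericMatrix& X, const std::vector<double>& y,
         const std::vector<int>& idx, int depth, int max_depth, int min_leaf,
         std::vector<Node>& nodes) {
  const int m = (int)idx.size();
  double sum = 0.0, sq = 0.0;
  for (int i : idx) { sum += y[i]; sq += y[i] * y[i]; }
  const double node_sse = sq - sum * sum / m;

  Node nd;
  nd.feat = -1;
  nd.thr = NA_REAL;
  nd.value = sum / m;
  nd.left = -1;
  nd.right = -1;
  const int me = (int)nodes.size();
  nodes.push_back(nd);

  // pure node (constant targets up to fp noise) stays a leaf
  if (depth >= max_depth || m < 2 * min_leaf ||
      node_sse <= 1e-12 * std::max(1.0, sq))
    return me;

  int bf = -1;
  double bt = 0.0, bs = 0.0;
  if (!find_best_split(X, y, idx, min_leaf, bf, bt, bs)) return me;
  if (!(bs < node_sse)) return me;  // require strict improvement

  std::vector<int> li, ri;
  li.reserve(m);
  ri.reserve(m);
  for (int i : idx) (X(i, bf) <= bt ? li : ri).push_back(i);

  nodes[me].feat = bf;
  nodes[me].thr = bt;
  const int l = grow(X, y, li, depth + 1, max_depth, min_leaf, nodes);
  const int r = grow(X, y, ri, depth + 1, max_depth, min_leaf, nodes);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

double predict_row(const std::vector<Node>& nodes, const NumericMatrix& X, int row) {
  int cur = 0;
  while (nodes[cur].feat >= 0)
    cur = (X(row, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left : nodes[cur].right;
  return nodes[cur].value;
}

List tree_to_list(const std::vector<Node>& nodes) {
  const int k = (int)nodes.size();
  IntegerVector feat(k), left(k), right(k);
  NumericVector thr(k), value(k);
  int leaves = 0;
  for (int i = 0; i < k; ++i) {
    if (nodes[i].feat < 0) {
      feat[i] = NA_INTEGER;
      thr[i] = NA_REAL;
      left[i] = NA_INTEGER;
      right[i] = NA_INTEGER;
      ++leaves;
    } else {
      feat[i] = nodes[i].feat + 1;   // 1-based for R
      thr[i] = nodes[i].thr;
      left[i] = nodes[i].left + 1;
      right[i] = nodes[i].right + 1;
    }
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feat, _["threshold"] = thr,
                      _["value"] = value, _["left"] = left, _["right"] = right,
                      _["n_leaves"] = leaves);
}

// Canonical row ordering (lexicographic over feature values, then target):
// fitting on rows in this order makes every floating-point accumulation, and
// hence the whole fit, invariant to the input sample order.
std::vector<int> canonical_order(const NumericMatrix& X, const NumericVector& y) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    for (int j = 0; j < p; ++j) {
      if (X(a, j) < X(b, j)) return true;
      if (X(a, j) > X(b, j)) return false;
    }
    return y[a] < y[b];
  });
  return ord;
}

struct GBRTFit {
  double beta0;
  std::vector<std::vector<Node>> trees;
  std::vector<double> beta;
  std::vector<double> loss;
  std::vector<double> fitted;
};

void fit_gbrt_canonical(const NumericMatrix& X, const NumericVector& y,
                        int M, double nu, int max_depth, int min_leaf,
                        GBRTFit& out) {
  const int n = y.size();
  double b0 = 0.0;
  for (int i = 0; i < n; ++i) b0 += y[i];
  b0 /= n;
  out.beta0 = b0;
  std::vector<double> f(n, b0), resid(n), h(n);
  std::vector<int> all(n);
  std::iota(all.begin(), all.end(), 0);

  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - f[i];  // -dPsi/dF for Psi = 1/2 (y-F)^2
    std::vector<Node> nodes;
    grow(X, resid, all, 0, max_depth, min_leaf, nodes);
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      h[i] = predict_row(nodes, X, i);
      num += h[i] * resid[i];
      den += h[i] * h[i];
    }
    const double beta = den > 0.0 ? num / den : 0.0;
    double loss = 0.0;
    for (int i = 0; i < n; ++i) {
      f[i] += nu * beta * h[i];
      const double e = y[i] - f[i];
      loss += 0.5 * e * e;
    }
    out.trees.push_back(std::move(nodes));
    out.beta.push_back(beta);
    out.loss.push_back(loss);
  }
  out.fitted.assign(f.begin(), f.end());
}

// reorder rows canonically, fit, and map fitted values back to input order
void fit_gbrt_internal(const NumericMatrix& X, const NumericVector& y,
                       int M, double nu, int max_depth, int min_leaf,
                       GBRTFit& out) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> ord = canonical_order(X, y);
  NumericMatrix Xs(n, p);
  NumericVector ys(n);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) Xs(r, j) = X(ord[r], j);
    ys[r] = y[ord[r]];
  }
  fit_gbrt_canonical(Xs, ys, M, nu, max_depth, min_leaf, out);
  std::vector<double> fitted(n);
  for (int r = 0; r < n; ++r) fitted[ord[r]] = out.fitted[r];
  out.fitted = fitted;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, int max_depth, int min_leaf) {
  const int n = y.size(), p = X.ncol();
  std::vector<int> ord = canonical_order(X, y);
  NumericMatrix Xs(n, p);
  std::vector<double> ys(n);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) Xs(r, j) = X(ord[r], j);
    ys[r] = y[ord[r]];
  }
  std::vector<int> all(n);
  std::iota(all.begin(), all.end(), 0);
  std::vector<Node> nodes;
  grow(Xs, ys, all, 0, max_depth, min_leaf, nodes);
  NumericVector fitted(n);
  for (int i = 0; i < n; ++i) fitted[i] = predict_row(nodes, X, i);
  List out = tree_to_list(nodes);
  out["fitted"] = fitted;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               NumericVector value, IntegerVector left,
                               IntegerVector right, NumericMatrix X) {
  const int k = feature.size(), n = X.nrow();
  std::vector<Node> nodes(k);
  for (int i = 0; i < k; ++i) {
    nodes[i].feat = feature[i] == NA_INTEGER ? -1 : feature[i] - 1;
    nodes[i].thr = threshold[i];
    nodes[i].value = value[i];
    nodes[i].left = left[i] == NA_INTEGER ? -1 : left[i] - 1;
    nodes[i].right = right[i] == NA_INTEGER ? -1 : right[i] - 1;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = predict_row(nodes, X, i);
  return out;
}

// [[Rcpp::export]]
List cpp_fit_gbrt(NumericMatrix X, NumericVector y, int M, double nu,
                  int max_depth, int min_leaf) {
  GBRTFit fit;
  fit_gbrt_internal(X, y, M, nu, max_depth, min_leaf, fit);
  List trees(M);
  for (int m = 0; m < M; ++m) trees[m] = tree_to_list(fit.trees[m]);
  return List::create(_["beta0"] = fit.beta0, _["trees"] = trees,
                      _["beta"] = NumericVector(fit.beta.begin(), fit.beta.end()),
                      _["train_loss"] = NumericVector(fit.loss.begin(), fit.loss.end()),
                      _["fitted"] = NumericVector(fit.fitted.begin(), fit.fitted.end()));
}

// Leave-one-out cross-validation, all folds fit in C++ for speed.
// [[Rcpp::export]]
NumericVector cpp_gbrt_loocv(NumericMatrix X, NumericVector y, int M, double nu,
                             int max_depth, int min_leaf) {
  const int n = y.size(), p = X.ncol();
  NumericVector out(n);
  NumericMatrix Xi(n - 1, p);
  NumericVector yi(n - 1);
  for (int hold = 0; hold < n; ++hold) {
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int j = 0; j < p; ++j) Xi(r, j) = X(i, j);
      yi[r] = y[i];
      ++r;
    }
    GBRTFit fit;
    fit_gbrt_internal(Xi, yi, M, nu, max_depth, min_leaf, fit);
    double pred = fit.beta0;
    for (int m = 0; m < M; ++m)
      pred += nu * fit.beta[m] * predict_row(fit.trees[m], X, hold);
    out[hold] = pred;
  }
  return out;
}
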