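#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Approximate entropy, Chebyshev distance, self-matches included.
// Phi_m(r) = mean_i ln C_i^m(r), C_i^m(r) = (#{j: max_k|u(i+k)-u(j+k)| <= r})
//            / (N - m + 1);  ApEn = Phi_m - Phi_{m+1}.
static double phi(const std::vector<double>& u, int m, double r) {
  const int N = (int)u.size();
  const int M = N - m + 1;            // number of template vectors
  double acc = 0.0;
  for (int i = 0; i < M; ++i) {
    int count = 0;
    for (int j = 0; j < M; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(u[i + k] - u[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) ++count;
    }
    acc += std::log((double)count / (double)M);
  }
  return acc / (double)M;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector samples, int m, double r) {
  const int N = samples.size();
  if (N < m + 2) stop("apen: series too short for m = %d", m);
  if (r <= 0) stop("apen: tolerance r must be > 0");
  std::vector<double> u(samples.begin(), samples.end());
  return phi(u, m, r) - phi(u, m + 1, r);
}

// ---------------------------------------------------------------------------
// Class-weighted decision tree.
// y is coded 0/1 (0 = abnormal, 1 = normal); w holds the two class weights
// in the same order. Node impurity is the Gini index of the weight-scaled
// class proportions p_k = w_k n_k / sum_j w_j n_j; the split score is the
// weighted-mass impurity decrease
//   G(parent) - (W_L/W) G(L) - (W_R/W) G(R).

static inline double gini2(double w0, double w1) {
  double W = w0 + w1;
  if (W <= 0) return 0.0;
  double p0 = w0 / W, p1 = w1 / W;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct SplitResult {
  int feature;       // 0-based, -1 if none
  double threshold;
  double gain;
};

// Best split over the given candidate features (0-based) for the rows
// (0-based into X). Thresholds are midpoints of consecutive distinct sorted
// values; ties broken toward the lowest feature index, then the lowest
// threshold (candidates are scanned in the order given; callers pass them
// sorted ascending when tie order matters).
static SplitResult best_split_impl(const NumericMatrix& X,
                                   const IntegerVector& y,
                                   const NumericVector& w,
                                   const std::vector<int>& rows,
                                   const std::vector<int>& cand,
                                   int min_leaf) {
  const int n = (int)rows.size();
  SplitResult best{-1, NA_REAL, 0.0};
  double n0 = 0, n1 = 0;
  for (int i = 0; i < n; ++i) (y[rows[i]] == 0 ? n0 : n1) += 1.0;
  const double W0 = w[0] * n0, W1 = w[1] * n1, W = W0 + W1;
  const double parent = gini2(W0, W1);
  if (parent <= 0.0) return best;

  std::vector<std::pair<double, int>> vals(n);  // (x value, class)
  for (int f : cand) {
    for (int i = 0; i < n; ++i) {
      vals[i] = {X(rows[i], f), y[rows[i]]};
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;  // constant
    double l0 = 0, l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      (vals[i].second == 0 ? l0 : l1) += 1.0;
      if (vals[i].first == vals[i + 1].first) continue;  // not a boundary
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double WL = w[0] * l0 + w[1] * l1;
      double WR = W - WL;
      double gain = parent - (WL / W) * gini2(w[0] * l0, w[1] * l1)
                           - (WR / W) * gini2(w[0] * (n0 - l0),
                                              w[1] * (n1 - l1));
      if (gain > best.gain + 1e-12) {
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        best.gain = gain;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                    IntegerVector rows, IntegerVector candidates,
                    int min_leaf = 1) {
  std::vector<int> rr(rows.begin(), rows.end());
  std::vector<int> cc(candidates.begin(), candidates.end());
  std::sort(cc.begin(), cc.end());
  SplitResult s = best_split_impl(X, y, w, rr, cc, min_leaf);
  return List::create(_["feature"] = s.feature < 0 ? NA_INTEGER
                                                   : s.feature + 1,
                      _["threshold"] = s.threshold,
                      _["gain"] = s.gain);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int mtry, min_leaf, p;
  std::vector<int> feature, left, right;
  std::vector<double> threshold, prob0, prob1;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              const NumericVector& w_, int mtry_, int min_leaf_)
      : X(X_), y(y_), w(w_), mtry(mtry_), min_leaf(min_leaf_),
        p(X_.ncol()) {}

  int new_node() {
    feature.push_back(-1); left.push_back(0); right.push_back(0);
    threshold.push_back(NA_REAL); prob0.push_back(0); prob1.push_back(0);
    return (int)feature.size() - 1;
  }

  // draw mtry distinct features via partial Fisher-Yates on R's RNG
  std::vector<int> draw_features() {
    std::vector<int> idx(p);
    for (int i = 0; i < p; ++i) idx[i] = i;
    int k = std::min(mtry, p);
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(idx[i], idx[j]);
    }
    std::vector<int> out(idx.begin(), idx.begin() + k);
    std::sort(out.begin(), out.end());   // deterministic tie order
    return out;
  }

  int grow(std::vector<int>& rows) {
    int id = new_node();
    double n0 = 0, n1 = 0;
    for (int r : rows) (y[r] == 0 ? n0 : n1) += 1.0;
    double W0 = w[0] * n0, W1 = w[1] * n1;
    prob0[id] = W0 / (W0 + W1);
    prob1[id] = W1 / (W0 + W1);
    // stop at purity or fewer than 2 samples; otherwise try a split
    if ((int)rows.size() >= 2 && n0 > 0 && n1 > 0) {
      std::vector<int> cand = draw_features();
      SplitResult s = best_split_impl(X, y, w, rows, cand, min_leaf);
      if (s.feature >= 0) {
        std::vector<int> lrows, rrows;
        lrows.reserve(rows.size()); rrows.reserve(rows.size());
        for (int r : rows) {
          (X(r, s.feature) <= s.threshold ? lrows : rrows).push_back(r);
        }
        feature[id] = s.feature;
        threshold[id] = s.threshold;
        int l = grow(lrows);
        int r = grow(rrows);
        left[id] = l;
        right[id] = r;
      }
    }
    return id;
  }
};

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                   IntegerVector rows, int mtry, int min_leaf = 1) {
  TreeBuilder tb(X, y, w, mtry, min_leaf);
  std::vector<int> rr(rows.begin(), rows.end());
  tb.grow(rr);
  int nn = (int)tb.feature.size();
  IntegerVector f(nn), l(nn), r(nn);
  NumericVector th(nn);
  NumericMatrix pr(nn, 2);
  for (int i = 0; i < nn; ++i) {
    f[i] = tb.feature[i] < 0 ? NA_INTEGER : tb.feature[i] + 1;  // 1-based
    l[i] = tb.left[i];    // 1-based child id + 1 handled below
    r[i] = tb.right[i];
    th[i] = tb.threshold[i];
    pr(i, 0) = tb.prob0[i];
    pr(i, 1) = tb.prob1[i];
  }
  // convert child indices to 1-based (0 stays 0 = leaf marker)
  for (int i = 0; i < nn; ++i) {
    if (!IntegerVector::is_na(f[i])) { l[i] += 1; r[i] += 1; }
    else { l[i] = 0; r[i] = 0; }
  }
  return List::create(_["feature"] = f, _["threshold"] = th,
                      _["left"] = l, _["right"] = r, _["prob"] = pr);
}

// Leaf class-probability rows for each row of X.
// [[Rcpp::export]]
NumericMatrix predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector f = tree["feature"], l = tree["left"], r = tree["right"];
  NumericVector th = tree["threshold"];
  NumericMatrix pr = tree["prob"];
  int n = X.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (!IntegerVector::is_na(f[node])) {
      node = (X(i, f[node] - 1) <= th[node]) ? l[node] - 1 : r[node] - 1;
    }
    out(i, 0) = pr(node, 0);
    out(i, 1) = pr(node, 1);
  }
  return out;
}
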