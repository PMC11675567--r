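// Weighted least-squares CART regression tree: the workhorse of the
// bagged forest and the boosting machine. Node-wise feature subsampling
// uses R's RNG so fits are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth, min_node, mtry;
  std::vector<int> feature;
  std::vector<double> threshold, value;
  std::vector<int> left, right;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_,
              const NumericVector& w_, int max_depth_, int min_node_,
              int mtry_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), min_node(min_node_),
        mtry(mtry_) {}

  int grow(std::vector<int>& idx, int depth) {
    int id = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(0.0);
    value.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);

    double sw = 0.0, swy = 0.0;
    for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; }
    value[id] = swy / sw;

    int n = (int)idx.size();
    bool pure = true;
    for (int i = 1; i < n; ++i)
      if (y[idx[i]] != y[idx[0]]) { pure = false; break; }
    if (depth >= max_depth || n < 2 * min_node || pure) return id;

    // sample mtry distinct features via R's RNG
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double best_gain = 1e-12, best_thr = 0.0;
    int best_f = -1;
    std::vector<int> ord(idx);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double cw = 0.0, cwy = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        int i = ord[k];
        cw += w[i];
        cwy += w[i] * y[i];
        if (X(ord[k], f) >= X(ord[k + 1], f)) continue;
        if (k + 1 < min_node || n - k - 1 < min_node) continue;
        double gain = cwy * cwy / cw +
                      (swy - cwy) * (swy - cwy) / (sw - cw) -
                      swy * swy / sw;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return id;
    feature[id] = best_f;
    threshold[id] = best_thr;
    left[id] = grow(li, depth + 1);
    right[id] = grow(ri, depth + 1);
    return id;
  }
};

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, int min_node, int mtry) {
  TreeBuilder tb(X, y, w, max_depth, min_node, mtry);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  tb.grow(idx, 0);
  return List::create(_["feature"] = tb.feature,
                      _["threshold"] = tb.threshold,
                      _["value"] = tb.value,
                      _["left"] = tb.left,
                      _["right"] = tb.right);
}

static int leaf_of(const IntegerVector& feature,
                   const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int row) {
  int id = 0;
  while (feature[id] >= 0) {
    id = (X(row, feature[id]) <= threshold[id]) ? left[id] : right[id];
  }
  return id;
}

// [[Rcpp::export(name = ".tree_leaf_cpp")]]
IntegerVector tree_leaf_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = leaf_of(feature, threshold, left, right, X, i) + 1;
  return out;
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = value[leaf_of(feature, threshold, left, right, X, i)];
  return out;
}
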