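// Compact regression random forest: bootstrap aggregation of CART trees with
// variance-reduction splits, per-node feature subsampling (mtry) and mean
// decrease in impurity (MDI) importances. Deterministic given the seed.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

static double node_sse(const std::vector<double>& ys) {
  double s = 0, s2 = 0;
  for (double v : ys) { s += v; s2 += v * v; }
  double n = (double)ys.size();
  return s2 - s * s / n;
}

static int grow(Tree& tree, const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int lo, int hi, int mtry,
                int min_split, std::mt19937& rng,
                std::vector<double>& importance, int n_train) {
  int node = (int)tree.feature.size();
  tree.feature.push_back(-1); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  int n = hi - lo;
  double sum = 0, sum2 = 0;
  for (int i = lo; i < hi; ++i) { double v = y[idx[i]]; sum += v; sum2 += v * v; }
  double mean = sum / n;
  tree.value.push_back(mean);
  double sse_parent = sum2 - sum * sum / n;
  if (n < min_split || sse_parent <= 1e-12) return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates: first mtry entries are the sampled features
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  int best_f = -1, best_pos = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> best_ord;
  for (int jj = 0; jj < mtry && jj < p; ++jj) {
    int f = feats[jj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double ls = 0, ls2 = 0, rs = sum, rs2 = sum2;
    for (int i = 0; i < n - 1; ++i) {
      double v = y[ord[i]];
      ls += v; ls2 += v * v; rs -= v; rs2 -= v * v;
      if (X(ord[i], f) == X(ord[i + 1], f)) continue;  // no split between ties
      int nl = i + 1, nr = n - nl;
      double sse = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
      double gain = sse_parent - sse;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_pos = i;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        best_ord = ord;
      }
    }
  }
  if (best_f < 0) return node;

  importance[best_f] += best_gain / n_train;
  std::copy(best_ord.begin(), best_ord.end(), idx.begin() + lo);
  int mid = lo + best_pos + 1;
  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = grow(tree, X, y, idx, lo, mid, mtry, min_split, rng, importance, n_train);
  tree.left[node] = l;
  int r = grow(tree, X, y, idx, mid, hi, mtry, min_split, rng, importance, n_train);
  tree.right[node] = r;
  return node;
}

static double tree_predict(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0)
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
      ? tree.left[node] : tree.right[node];
  return tree.value[node];
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
            int min_split, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(n_trees);
  NumericVector importance(p);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    std::vector<double> imp(p, 0.0);
    grow(tree, X, y, idx, 0, n, mtry, min_split, rng, imp, n);
    double tot = 0;
    for (int j = 0; j < p; ++j) tot += imp[j];
    if (tot > 0)
      for (int j = 0; j < p; ++j) importance[j] += imp[j] / tot / n_trees;
    trees[t] = List::create(_["feature"] = wrap(tree.feature),
                            _["threshold"] = wrap(tree.threshold),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["value"] = wrap(tree.value));
  }
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    Tree tree;
    tree.feature = as<std::vector<int>>(tl["feature"]);
    tree.threshold = as<std::vector<double>>(tl["threshold"]);
    tree.left = as<std::vector<int>>(tl["left"]);
    tree.right = as<std::vector<int>>(tl["right"]);
    tree.value = as<std::vector<double>>(tl["value"]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
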