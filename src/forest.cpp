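#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// Minimal regression random forest (CART trees, variance-reduction splits,
// bootstrap resampling, mtry features per split, impurity importances).
// Deterministic for a given seed: all randomness comes from one mt19937
// stream, independent of R's RNG.

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  double value;    // leaf prediction (node mean)
  int left, right; // child indices
};

struct Tree {
  std::vector<Node> nodes;
};

static void grow(Tree &tree, int node_id,
                 const NumericMatrix &X, const NumericVector &y,
                 std::vector<int> &idx, int lo, int hi,
                 int mtry, int min_node, std::mt19937 &rng,
                 std::vector<double> &importance) {
  int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int t = lo; t < hi; ++t) { double v = y[idx[t]]; sum += v; sum2 += v * v; }
  double mean = sum / n;
  tree.nodes[node_id].value = mean;
  tree.nodes[node_id].feature = -1;
  double sse = sum2 - sum * sum / n;
  if (n < 2 * min_node || sse <= 1e-12) return;

  int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  int m = std::min(mtry, p);
  for (int f = 0; f < m; ++f) {
    std::uniform_int_distribution<int> U(f, p - 1);
    std::swap(feats[f], feats[U(rng)]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  std::vector<std::pair<double, double>> xy(n);
  for (int f = 0; f < m; ++f) {
    int feat = feats[f];
    for (int t = 0; t < n; ++t) {
      int i = idx[lo + t];
      xy[t] = std::make_pair(X(i, feat), y[i]);
    }
    std::sort(xy.begin(), xy.end());
    if (xy[0].first == xy[n - 1].first) continue;
    double sl = 0.0;
    for (int t = 0; t < n - 1; ++t) {
      sl += xy[t].second;
      if (xy[t].first == xy[t + 1].first) continue;
      int nl = t + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double sr = sum - sl;
      double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = feat;
        best_thr = 0.5 * (xy[t].first + xy[t + 1].first);
      }
    }
  }
  if (best_feat < 0) return;

  // partition idx[lo,hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_feat) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return; // numeric ties; give up splitting

  importance[best_feat] += best_gain;
  tree.nodes[node_id].feature = best_feat;
  tree.nodes[node_id].threshold = best_thr;
  int l = (int) tree.nodes.size(); tree.nodes.push_back(Node());
  int r = (int) tree.nodes.size(); tree.nodes.push_back(Node());
  tree.nodes[node_id].left = l;
  tree.nodes[node_id].right = r;
  grow(tree, l, X, y, idx, lo, mid, mtry, min_node, rng, importance);
  grow(tree, r, X, y, idx, mid, hi, mtry, min_node, rng, importance);
}

static double predict_one(const Tree &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree.nodes[node].feature >= 0) {
    node = (X(row, tree.nodes[node].feature) <= tree.nodes[node].threshold)
      ? tree.nodes[node].left : tree.nodes[node].right;
  }
  return tree.nodes[node].value;
}

// [[Rcpp::export(name = ".rf_fit_predict")]]
List rf_fit_predict(NumericMatrix X, NumericVector y, NumericMatrix Xtest,
                    int ntree, int mtry, int min_node, int seed) {
  int n = X.nrow(), p = X.ncol(), ntst = Xtest.nrow();
  if (Xtest.ncol() != p) stop("feature count mismatch between train and test");
  std::mt19937 rng((unsigned) seed);
  std::uniform_int_distribution<int> B(0, n - 1);
  std::vector<double> importance(p, 0.0);
  NumericVector pred(ntst, 0.0);
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = B(rng); // bootstrap
    Tree tree;
    tree.nodes.push_back(Node());
    grow(tree, 0, X, y, idx, 0, n, mtry, min_node, rng, importance);
    for (int i = 0; i < ntst; ++i) pred[i] += predict_one(tree, Xtest, i);
  }
  if (ntst > 0) for (int i = 0; i < ntst; ++i) pred[i] /= ntree;
  NumericVector imp(p);
  double tot = 0.0;
  for (int f = 0; f < p; ++f) tot += importance[f];
  for (int f = 0; f < p; ++f) imp[f] = (tot > 0) ? importance[f] / tot : 0.0;
  return List::create(_["pred"] = pred, _["importance"] = imp);
}
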