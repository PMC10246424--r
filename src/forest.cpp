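#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Regression random forest (CART trees, variance-reduction splits, bootstrap
// resampling, mtry feature subsampling). All randomness is drawn from R's RNG
// so results are reproducible under set.seed().

namespace {

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> val;
};

int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void grow_node(Tree& tree, const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int lo, int hi, int mtry, int min_split,
               std::vector<int>& feat_pool) {
  int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; ss += y[idx[i]] * y[idx[i]]; }
  int node = (int)tree.feat.size();
  tree.feat.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.val.push_back(sum / n);

  double sse = ss - sum * sum / n;
  if (n < min_split || sse <= 1e-12) return;

  int p = X.ncol();
  // partial Fisher-Yates over the feature pool
  for (int j = 0; j < mtry; ++j) {
    int k = j + rand_int(p - j);
    std::swap(feat_pool[j], feat_pool[k]);
  }

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, double> > xy(n);
  for (int j = 0; j < mtry; ++j) {
    int f = feat_pool[j];
    for (int i = 0; i < n; ++i)
      xy[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(xy.begin(), xy.end());
    if (xy[0].first == xy[n - 1].first) continue;
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += xy[i].second;
      if (xy[i].first == xy[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      double gain = sl * sl / nl + (sum - sl) * (sum - sl) / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // in-place partition of idx[lo:hi)
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;

  tree.feat[node] = best_f;
  tree.thr[node] = best_thr;
  tree.left[node] = (int)tree.feat.size();
  grow_node(tree, X, y, idx, lo, mid, mtry, min_split, feat_pool);
  tree.right[node] = (int)tree.feat.size();
  grow_node(tree, X, y, idx, mid, hi, mtry, min_split, feat_pool);
}

double predict_one(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feat[node] >= 0)
    node = (X(row, t.feat[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  return t.val[node];
}

List pack(const Tree& t) {
  return List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["val"] = wrap(t.val));
}

Tree unpack(const List& l) {
  Tree t;
  t.feat = as<std::vector<int> >(l["feat"]);
  t.thr = as<std::vector<double> >(l["thr"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.val = as<std::vector<double> >(l["val"]);
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                     int min_split) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List trees(n_trees);
  std::vector<int> pool(p);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);  // bootstrap
    for (int j = 0; j < p; ++j) pool[j] = j;
    Tree t;
    grow_node(t, X, y, idx, 0, n, mtry, min_split, pool);
    trees[b] = pack(t);
  }
  return trees;
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    Tree t = unpack(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(t, X, i);
  }
  return out / (double)B;
}

// permutation importance on a held-out set: mean increase in MSE over
// n_perm within-column shuffles (R RNG), relative to the unpermuted MSE.
// [[Rcpp::export(name = ".perm_importance_cpp")]]
NumericVector perm_importance_cpp(List trees, NumericMatrix X,
                                  NumericVector y, int n_perm) {
  int n = X.nrow(), p = X.ncol(), B = trees.size();
  std::vector<Tree> forest(B);
  for (int b = 0; b < B; ++b) forest[b] = unpack(trees[b]);

  NumericMatrix Xw(clone(X));
  std::vector<double> pred(n);
  // tree-outer accumulation keeps each tree's arrays hot in cache
  auto ensemble_mse = [&](double* out_pred) {
    std::fill(out_pred, out_pred + n, 0.0);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < n; ++i) out_pred[i] += predict_one(forest[b], Xw, i);
    double mse = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = out_pred[i] / B - y[i];
      mse += d * d;
    }
    return mse / n;
  };
  double base = ensemble_mse(pred.data());

  NumericVector imp(p);
  std::vector<double> col(n);
  std::vector<int> perm(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = Xw(i, j);
    double acc = 0.0;
    for (int r = 0; r < n_perm; ++r) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[rand_int(i + 1)]);
      for (int i = 0; i < n; ++i) Xw(i, j) = col[perm[i]];
      acc += ensemble_mse(pred.data());
    }
    for (int i = 0; i < n; ++i) Xw(i, j) = col[i];
    imp[j] = acc / n_perm - base;
    if (imp[j] < 0) imp[j] = 0;
  }
  imp.attr("base_mse") = base;
  return imp;
}
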