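// Decision-tree learners backing the random-forest and gradient-boosting
// classifier families.  All randomness (bootstrap, feature subsampling)
// comes from R's RNG so that set.seed() on the R side fixes the model.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;       // -1 => leaf
  std::vector<double> threshold;
  std::vector<int> left, right;   // -1 => none
  std::vector<std::vector<double>> value;  // class distribution / leaf mean
};

int r_sample_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Draw `take` distinct feature indices from 0..p-1 (partial Fisher-Yates).
void sample_features(std::vector<int>& pool, int take) {
  int p = (int)pool.size();
  for (int i = 0; i < take; ++i) {
    int j = i + r_sample_int(p - i);
    std::swap(pool[i], pool[j]);
  }
}

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double score = -1.0;  // impurity decrease; <=0 means no usable split
};

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (n * n);
}

// Best gini split for a classification node over candidate features.
Split best_cls_split(const NumericMatrix& X, const IntegerVector& y, int K,
                     const std::vector<int>& rows,
                     const std::vector<int>& feats, int nfeat) {
  int n = (int)rows.size();
  std::vector<double> total(K, 0.0);
  for (int r : rows) total[y[r]] += 1.0;
  double parent = gini_from_counts(total, n);

  Split best;
  std::vector<std::pair<double, int>> vals(n);
  for (int fi = 0; fi < nfeat; ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) vals[i] = {X(rows[i], f), y[rows[i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::vector<double> leftc(K, 0.0);
    double nl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      leftc[vals[i].second] += 1.0;
      nl += 1.0;
      if (vals[i].first == vals[i + 1].first) continue;
      double nr = n - nl;
      std::vector<double> rightc(K);
      for (int k = 0; k < K; ++k) rightc[k] = total[k] - leftc[k];
      double g = parent - (nl / n) * gini_from_counts(leftc, nl)
                        - (nr / n) * gini_from_counts(rightc, nr);
      if (g > best.score + 1e-12) {
        best.score = g;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  return best;
}

// Best variance-reduction split for a regression node.
Split best_reg_split(const NumericMatrix& X, const NumericVector& resp,
                     const std::vector<int>& rows,
                     const std::vector<int>& feats, int nfeat) {
  int n = (int)rows.size();
  double tot = 0.0, tot2 = 0.0;
  for (int r : rows) { tot += resp[r]; tot2 += resp[r] * resp[r]; }
  double parent_sse = tot2 - tot * tot / n;

  Split best;
  std::vector<std::pair<double, double>> vals(n);
  for (int fi = 0; fi < nfeat; ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) vals[i] = {X(rows[i], f), resp[rows[i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double sl = 0.0, sl2 = 0.0, nl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += vals[i].second;
      sl2 += vals[i].second * vals[i].second;
      nl += 1.0;
      if (vals[i].first == vals[i + 1].first) continue;
      double nr = n - nl;
      double sse_l = sl2 - sl * sl / nl;
      double sr = tot - sl, sr2 = tot2 - sl2;
      double sse_r = sr2 - sr * sr / nr;
      double g = parent_sse - sse_l - sse_r;
      if (g > best.score + 1e-12) {
        best.score = g;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  return best;
}

int grow(TreeNodes& tr, const NumericMatrix& X, const IntegerVector& y,
         const NumericVector& resp, bool classify, int K,
         std::vector<int>& rows, int depth, int max_depth, int min_node,
         int mtry, std::vector<int>& feat_pool,
         std::vector<int>* leaf_of_row) {
  int node = (int)tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  int n = (int)rows.size();

  std::vector<double> val;
  bool pure = false;
  if (classify) {
    val.assign(K, 0.0);
    for (int r : rows) val[y[r]] += 1.0;
    int nonzero = 0;
    for (int k = 0; k < K; ++k) if (val[k] > 0) ++nonzero;
    pure = nonzero <= 1;
    for (int k = 0; k < K; ++k) val[k] /= n;
  } else {
    double m = 0.0;
    for (int r : rows) m += resp[r];
    val.assign(1, m / n);
  }
  tr.value.push_back(val);

  bool make_leaf = pure || depth >= max_depth || n < 2 * min_node;
  Split sp;
  if (!make_leaf) {
    sample_features(feat_pool, mtry);
    sp = classify ? best_cls_split(X, y, K, rows, feat_pool, mtry)
                  : best_reg_split(X, resp, rows, feat_pool, mtry);
    if (sp.feature < 0) make_leaf = true;
  }
  if (make_leaf) {
    if (leaf_of_row) for (int r : rows) (*leaf_of_row)[r] = node;
    return node;
  }

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, sp.feature) <= sp.threshold) lrows.push_back(r);
    else rrows.push_back(r);
  }
  rows.clear(); rows.shrink_to_fit();
  tr.feature[node] = sp.feature;
  tr.threshold[node] = sp.threshold;
  int l = grow(tr, X, y, resp, classify, K, lrows, depth + 1, max_depth,
               min_node, mtry, feat_pool, leaf_of_row);
  int r = grow(tr, X, y, resp, classify, K, rrows, depth + 1, max_depth,
               min_node, mtry, feat_pool, leaf_of_row);
  tr.left[node] = l;
  tr.right[node] = r;
  return node;
}

List tree_to_list(const TreeNodes& tr, int width) {
  int n = (int)tr.feature.size();
  NumericMatrix value(n, width);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < width; ++k) value(i, k) = tr.value[i][k];
  return List::create(
    _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
    _["threshold"] = NumericVector(tr.threshold.begin(), tr.threshold.end()),
    _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
    _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
    _["value"] = value);
}

int descend(const IntegerVector& feature, const NumericVector& threshold,
            const IntegerVector& left, const IntegerVector& right,
            const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export(rng = true)]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_classes,
                    int n_trees, int mtry, int max_depth, int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List forest(n_trees);
  std::vector<int> feat_pool(p);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = r_sample_int(n);  // bootstrap
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    TreeNodes tr;
    grow(tr, X, y, NumericVector(0), true, n_classes, rows, 0, max_depth,
         min_node, mtry, feat_pool, nullptr);
    forest[t] = tree_to_list(tr, n_classes);
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_predict(List forest, NumericMatrix X,
                                 int n_classes) {
  int n = X.nrow(), T = forest.size();
  NumericMatrix out(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(feature, threshold, left, right, X, i);
      for (int k = 0; k < n_classes; ++k) out(i, k) += value(leaf, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_classes; ++k) out(i, k) /= T;
  return out;
}

// [[Rcpp::export(rng = true)]]
List cpp_reg_tree_fit(NumericMatrix X, NumericVector resp, int max_depth,
                      int min_node, int mtry) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  std::vector<int> leaf_of_row(n, 0);
  TreeNodes tr;
  grow(tr, X, IntegerVector(0), resp, false, 1, rows, 0, max_depth, min_node,
       mtry, feat_pool, &leaf_of_row);
  List tree = tree_to_list(tr, 1);
  tree["train_leaf"] = IntegerVector(leaf_of_row.begin(), leaf_of_row.end());
  return tree;
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = descend(feature, threshold, left, right, X, i);
  return out;
}
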