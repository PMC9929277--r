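#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat-array binary tree grower shared by the decision tree, random forest
// and gradient-boosting wrappers on the R side.
//
// mode 0: binary classification, entropy (information-gain) splits,
//         leaf value = class-1 fraction.
// mode 1: regression on y (pseudo-residuals), SSE splits, Newton leaf
//         value = sum(y) / sum(h) for hessian weights h.
//
// Split rule: x <= threshold goes left. Feature subsampling per node uses
// R's RNG (deterministic under set.seed on the R side).

namespace {

struct Tree {
  std::vector<int> var, left, right, n;
  std::vector<double> thr, value;
};

double entropy(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  double h = 0.0;
  if (p > 0.0) h -= p * std::log(p);
  if (p < 1.0) h -= (1.0 - p) * std::log(1.0 - p);
  return h;
}

class Grower {
public:
  Grower(const NumericMatrix& X, const NumericVector& y,
         const NumericVector& h, int mtry, int max_depth, int min_node,
         int mode, double min_hess)
    : X_(X), y_(y), h_(h), mtry_(mtry), max_depth_(max_depth),
      min_node_(min_node), mode_(mode), min_hess_(min_hess),
      p_(X.ncol()) {
    feat_.resize(p_);
    for (int j = 0; j < p_; ++j) feat_[j] = j;
  }

  Tree tree;

  int build(std::vector<int>& rows, int depth) {
    const int n = (int)rows.size();
    double sy = 0.0, sh = 0.0, syy = 0.0;
    for (int r : rows) { sy += y_[r]; sh += h_[r]; syy += y_[r] * y_[r]; }
    const double leaf_val = (mode_ == 0)
      ? sy / n
      : (sh > 1e-12 ? sy / sh : 0.0);
    bool pure = (mode_ == 0)
      ? (sy < 1e-12 || sy > n - 1e-12)
      : (syy - sy * sy / n < 1e-12);
    if (depth >= max_depth_ || n < min_node_ || pure)
      return push_leaf(leaf_val, n);

    // sample mtry candidate features without replacement (R RNG)
    for (int j = p_ - 1; j > 0; --j) {
      int k = (int)(unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(feat_[j], feat_[k]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > xs(n);
    const double parent_imp = (mode_ == 0) ? entropy(sy, n) : 0.0;

    for (int jj = 0; jj < std::min(mtry_, p_); ++jj) {
      const int f = feat_[jj];
      for (int i = 0; i < n; ++i) xs[i] = std::make_pair(X_(rows[i], f), rows[i]);
      std::sort(xs.begin(), xs.end());
      if (xs.front().first == xs.back().first) continue;
      double ly = 0.0, lh = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        const int r = xs[i].second;
        ly += y_[r]; lh += h_[r];
        if (xs[i].first == xs[i + 1].first) continue;
        // hessian-weight floor per child (regression/boosting mode only)
        if (mode_ == 1 && (lh < min_hess_ || sh - lh < min_hess_)) continue;
        const int nl = i + 1, nr = n - nl;
        double gain;
        if (mode_ == 0) {
          gain = parent_imp - ((double)nl / n) * entropy(ly, nl)
                            - ((double)nr / n) * entropy(sy - ly, nr);
        } else {
          // SSE reduction = Sl^2/nl + Sr^2/nr - S^2/n
          const double sr = sy - ly;
          gain = ly * ly / nl + sr * sr / nr - sy * sy / n;
        }
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = xs[i].first + 0.5 * (xs[i + 1].first - xs[i].first);
        }
      }
    }

    if (best_f < 0) return push_leaf(leaf_val, n);

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int r : rows) {
      if (X_(r, best_f) <= best_thr) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) return push_leaf(leaf_val, n);

    const int id = push_leaf(leaf_val, n);  // placeholder, fill below
    tree.var[id] = best_f;
    tree.thr[id] = best_thr;
    const int lid = build(lrows, depth + 1);
    tree.left[id] = lid;
    const int rid = build(rrows, depth + 1);
    tree.right[id] = rid;
    return id;
  }

private:
  int push_leaf(double val, int n) {
    tree.var.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(val);
    tree.n.push_back(n);
    return (int)tree.var.size() - 1;
  }

  const NumericMatrix& X_;
  const NumericVector& y_;
  const NumericVector& h_;
  int mtry_, max_depth_, min_node_, mode_;
  double min_hess_;
  int p_;
  std::vector<int> feat_;
};

double predict_one(const IntegerVector& var, const NumericVector& thr,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericVector& value,
                   const NumericMatrix& X, int row) {
  int node = 0;
  while (var[node] >= 0)
    node = (X(row, var[node]) <= thr[node]) ? left[node] : right[node];
  return value[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, NumericVector h,
                   IntegerVector rows, int mtry, int max_depth,
                   int min_node, int mode, double min_hess = 0.0) {
  std::vector<int> rv(rows.begin(), rows.end());
  Grower g(X, y, h, mtry, max_depth, min_node, mode, min_hess);
  g.build(rv, 0);
  return List::create(
    _["var"] = IntegerVector(g.tree.var.begin(), g.tree.var.end()),
    _["thr"] = NumericVector(g.tree.thr.begin(), g.tree.thr.end()),
    _["left"] = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
    _["right"] = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
    _["value"] = NumericVector(g.tree.value.begin(), g.tree.value.end()),
    _["n"] = IntegerVector(g.tree.n.begin(), g.tree.n.end()));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(var, thr, left, right, value, X, i);
  return out;
}

// type 0: mean of tree values; type 1: fraction of trees whose value >= 0.5
// (majority vote); type 2: sum of tree values (boosting raw margin).
// [[Rcpp::export]]
NumericVector cpp_predict_ensemble(List trees, NumericMatrix X, int type) {
  const int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
    NumericVector thr = tree["thr"], value = tree["value"];
    for (int i = 0; i < n; ++i) {
      double v = predict_one(var, thr, left, right, value, X, i);
      if (type == 1) out[i] += (v >= 0.5) ? 1.0 : 0.0;
      else out[i] += v;
    }
  }
  if (type == 0 || type == 1)
    for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
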