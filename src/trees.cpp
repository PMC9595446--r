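// Tree learners shared by the RF / XGB classifier schemes and the isolation
// forest operator. Plain Rcpp; cohorts in scope are small (n, p <= a few
// hundred) so a straightforward vector-backed CART is ample.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct FlatTree {
  // node arrays; leaf iff feat == -1, then `value` is the leaf output
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;

  int add_leaf(double v) {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); value.push_back(v);
    return (int)feat.size() - 1;
  }
  int add_split(int f, double t) {
    feat.push_back(f); thr.push_back(t);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    return (int)feat.size() - 1;
  }
  List as_list() const {
    return List::create(_["feat"] = wrap(feat), _["thr"] = wrap(thr),
                        _["left"] = wrap(left), _["right"] = wrap(right),
                        _["value"] = wrap(value));
  }
};

double predict_one(const IntegerVector& feat, const NumericVector& thr,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericVector& value, const NumericMatrix& X, int row) {
  int node = 0;
  while (feat[node] >= 0) {
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  }
  return value[node];
}

// variance-criterion CART used for the classification forest (binary y in
// {0,1}: SSE reduction orders splits identically to Gini)
struct CartBuilder {
  const NumericMatrix& X;
  const std::vector<double>& y;
  int mtry, min_node, max_depth;
  std::mt19937& rng;
  FlatTree tree;
  std::vector<int> feat_pool;

  CartBuilder(const NumericMatrix& X_, const std::vector<double>& y_,
              int mtry_, int min_node_, int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(rng_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int grow(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
    double mean = sum / n;
    double sse = sum2 - sum * sum / n;
    if (depth >= max_depth || n < 2 * min_node || sse <= 1e-12)
      return tree.add_leaf(mean);

    // partial Fisher-Yates draw of mtry candidate features
    int p = (int)feat_pool.size();
    int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k) {
      std::uniform_int_distribution<int> pick(k, p - 1);
      std::swap(feat_pool[k], feat_pool[pick(rng)]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_score = sse - 1e-12;
    std::vector<std::pair<double, double>> vy(n);
    for (int k = 0; k < m; ++k) {
      int f = feat_pool[k];
      for (int i = 0; i < n; ++i) vy[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vy.begin(), vy.end());
      if (vy.front().first == vy.back().first) continue;
      double ls = 0.0, ls2 = 0.0, rs = sum, rs2 = sum2;
      for (int i = 0; i < n - 1; ++i) {
        double yv = vy[i].second;
        ls += yv; ls2 += yv * yv; rs -= yv; rs2 -= yv * yv;
        if (vy[i].first == vy[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double score = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
        if (score < best_score) {
          best_score = score;
          best_f = f;
          best_thr = vy[i].first + 0.5 * (vy[i + 1].first - vy[i].first);
        }
      }
    }
    if (best_f < 0) return tree.add_leaf(mean);

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return tree.add_leaf(mean);
    int node = tree.add_split(best_f, best_thr);
    int l = grow(lidx, depth + 1);
    int r = grow(ridx, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                     int min_node, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  std::vector<double> yv(y.begin(), y.end());
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    CartBuilder b(X, yv, mtry, min_node, max_depth, rng);
    b.grow(idx, 0);
    trees[t] = b.tree.as_list();
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], value = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_one(feat, thr, left, right, value, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

namespace {

// second-order (Newton) regression tree on gradient/hessian vectors,
// exhaustive split search, gain as in gradient-boosted tree learners
struct GhBuilder {
  const NumericMatrix& X;
  const NumericVector& g;
  const NumericVector& h;
  int max_depth, min_node;
  double lambda;
  FlatTree tree;

  GhBuilder(const NumericMatrix& X_, const NumericVector& g_,
            const NumericVector& h_, int max_depth_, int min_node_, double lambda_)
      : X(X_), g(g_), h(h_), max_depth(max_depth_), min_node(min_node_),
        lambda(lambda_) {}

  int grow(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    double leaf_val = -G / (H + lambda);
    if (depth >= max_depth || n < 2 * min_node) return tree.add_leaf(leaf_val);

    double parent = G * G / (H + lambda);
    int best_f = -1;
    double best_thr = 0.0, best_gain = 1e-10;
    int p = X.ncol();
    std::vector<std::pair<double, int>> vi(n);
    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n; ++i) vi[i] = {X(idx[i], f), idx[i]};
      std::sort(vi.begin(), vi.end());
      if (vi.front().first == vi.back().first) continue;
      double GL = 0.0, HL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        GL += g[vi[i].second]; HL += h[vi[i].second];
        if (vi[i].first == vi[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double GR = G - GL, HR = H - HL;
        double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = vi[i].first + 0.5 * (vi[i + 1].first - vi[i].first);
        }
      }
    }
    if (best_f < 0) return tree.add_leaf(leaf_val);
    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    int node = tree.add_split(best_f, best_thr);
    int l = grow(lidx, depth + 1);
    int r = grow(ridx, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_fit_tree_gh(NumericMatrix X, NumericVector g, NumericVector h,
                     int max_depth, int min_node, double lambda) {
  GhBuilder b(X, g, h, max_depth, min_node, lambda);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.grow(idx, 0);
  return b.tree.as_list();
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tr, NumericMatrix X) {
  IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
  NumericVector thr = tr["thr"], value = tr["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(feat, thr, left, right, value, X, i);
  return out;
}

namespace {

double iforest_c(int n) {
  if (n <= 1) return 0.0;
  if (n == 2) return 1.0;
  const double euler = 0.5772156649015329;
  return 2.0 * (std::log((double)(n - 1)) + euler) - 2.0 * (n - 1) / (double)n;
}

struct IsoTree {
  std::vector<int> feat;        // -1 for external node
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> size;        // training size at external node

  int build(const NumericMatrix& X, std::vector<int>& idx, int depth,
            int depth_limit, std::mt19937& rng) {
    int n = (int)idx.size();
    if (n <= 1 || depth >= depth_limit) {
      feat.push_back(-1); thr.push_back(0); left.push_back(-1);
      right.push_back(-1); size.push_back(n);
      return (int)feat.size() - 1;
    }
    // candidate features with spread inside this node
    std::vector<int> cand;
    for (int f = 0; f < X.ncol(); ++f) {
      double lo = X(idx[0], f), hi = lo;
      for (int i : idx) { lo = std::min(lo, X(i, f)); hi = std::max(hi, X(i, f)); }
      if (hi > lo) cand.push_back(f);
    }
    if (cand.empty()) {
      feat.push_back(-1); thr.push_back(0); left.push_back(-1);
      right.push_back(-1); size.push_back(n);
      return (int)feat.size() - 1;
    }
    std::uniform_int_distribution<int> pickf(0, (int)cand.size() - 1);
    int f = cand[pickf(rng)];
    double lo = X(idx[0], f), hi = lo;
    for (int i : idx) { lo = std::min(lo, X(i, f)); hi = std::max(hi, X(i, f)); }
    std::uniform_real_distribution<double> pickt(lo, hi);
    double t = pickt(rng);
    std::vector<int> lidx, ridx;
    for (int i : idx) { if (X(i, f) < t) lidx.push_back(i); else ridx.push_back(i); }
    if (lidx.empty() || ridx.empty()) {
      feat.push_back(-1); thr.push_back(0); left.push_back(-1);
      right.push_back(-1); size.push_back(n);
      return (int)feat.size() - 1;
    }
    feat.push_back(f); thr.push_back(t); left.push_back(-2); right.push_back(-2);
    size.push_back(n);
    int node = (int)feat.size() - 1;
    int l = build(X, lidx, depth + 1, depth_limit, rng);
    int r = build(X, ridx, depth + 1, depth_limit, rng);
    left[node] = l; right[node] = r;
    return node;
  }

  double path_length(const NumericMatrix& X, int row) const {
    int node = 0, depth = 0;
    while (feat[node] >= 0) {
      node = (X(row, feat[node]) < thr[node]) ? left[node] : right[node];
      ++depth;
    }
    return depth + iforest_c(size[node]);
  }
};

}  // namespace

// average isolation path length per row; anomaly score computed in R as
// 2^(-E[h]/c(psi))
// [[Rcpp::export]]
NumericVector cpp_isolation_depths(NumericMatrix X, int n_trees, int psi, int seed) {
  int n = X.nrow();
  psi = std::min(psi, n);
  int depth_limit = (int)std::ceil(std::log2((double)std::max(psi, 2)));
  std::mt19937 rng((unsigned)seed);
  NumericVector depths(n, 0.0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  for (int t = 0; t < n_trees; ++t) {
    // partial Fisher-Yates subsample of psi rows
    std::vector<int> pool = all;
    for (int k = 0; k < psi; ++k) {
      std::uniform_int_distribution<int> pick(k, n - 1);
      std::swap(pool[k], pool[pick(rng)]);
    }
    std::vector<int> idx(pool.begin(), pool.begin() + psi);
    IsoTree tr;
    tr.build(X, idx, 0, depth_limit, rng);
    for (int i = 0; i < n; ++i) depths[i] += tr.path_length(X, i);
  }
  for (int i = 0; i < n; ++i) depths[i] /= n_trees;
  return depths;
}

// [[Rcpp::export]]
double cpp_iforest_cn(int n) { return iforest_c(n); }
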