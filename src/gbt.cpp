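// Gradient-boosted trees for binary classification, logistic loss.
// Second-order (gain-based) splits and leaf weights; deterministic:
// no RNG, features scanned in column order, strictly-greater gain wins.
// Feature columns are presorted once per fit; each node walks the
// presorted order through a membership stamp, so split search is
// O(n * p) per node regardless of depth.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child indices, -1 for leaf
  double value;    // leaf weight (learning rate already applied)
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

inline double leaf_objective(double G, double H, double lambda) {
  return (G * G) / (H + lambda);
}

struct FitWorkspace {
  std::vector<std::vector<int>> order; // per feature, row indices sorted by value
  std::vector<int> stamp;              // node-membership stamp per row
  std::vector<int> features;           // features available to the current tree
  int cur_stamp = 0;
};

SplitResult best_split(const NumericMatrix& X,
                       const std::vector<double>& grad,
                       const std::vector<double>& hess,
                       const std::vector<int>& idx,
                       const FitWorkspace& ws,
                       double lambda, int min_obs) {
  SplitResult best;
  const int n = (int)idx.size();
  double G = 0.0, H = 0.0;
  for (int i : idx) { G += grad[i]; H += hess[i]; }
  const double parent_obj = leaf_objective(G, H, lambda);

  for (int f : ws.features) {
    const std::vector<int>& ord = ws.order[f];
    double GL = 0.0, HL = 0.0;
    int cnt = 0;
    double prev_val = 0.0;
    for (int i : ord) {
      if (ws.stamp[i] != ws.cur_stamp) continue;
      const double v = X(i, f);
      if (cnt > 0 && v > prev_val && cnt >= min_obs && (n - cnt) >= min_obs) {
        const double GR = G - GL, HR = H - HL;
        const double gain = 0.5 * (leaf_objective(GL, HL, lambda) +
                                   leaf_objective(GR, HR, lambda) - parent_obj);
        if (gain > best.gain) {
          best.gain = gain;
          best.feature = f;
          best.threshold = 0.5 * (prev_val + v);
        }
      }
      GL += grad[i];
      HL += hess[i];
      ++cnt;
      prev_val = v;
    }
  }
  return best;
}

void build_tree(const NumericMatrix& X,
                const std::vector<double>& grad,
                const std::vector<double>& hess,
                const std::vector<int>& idx,
                int depth, int max_depth, double lambda, int min_obs,
                double learning_rate, FitWorkspace& ws,
                std::vector<Node>& nodes, int node_id,
                std::vector<double>& importance,
                std::vector<double>& margin_update) {
  SplitResult sp;
  if (depth < max_depth && (int)idx.size() >= 2 * min_obs) {
    ++ws.cur_stamp;
    for (int i : idx) ws.stamp[i] = ws.cur_stamp;
    sp = best_split(X, grad, hess, idx, ws, lambda, min_obs);
  }

  if (sp.feature < 0 || sp.gain <= 0.0) {
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += grad[i]; H += hess[i]; }
    const double w = -G / (H + lambda) * learning_rate;
    nodes[node_id].feature = -1;
    nodes[node_id].value = w;
    for (int i : idx) margin_update[i] = w;
    return;
  }
  importance[sp.feature] += sp.gain;
  nodes[node_id].feature = sp.feature;
  nodes[node_id].threshold = sp.threshold;

  std::vector<int> left_idx, right_idx;
  for (int i : idx) {
    if (X(i, sp.feature) < sp.threshold) left_idx.push_back(i);
    else right_idx.push_back(i);
  }
  const int li = (int)nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  const int ri = (int)nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  build_tree(X, grad, hess, left_idx, depth + 1, max_depth, lambda, min_obs,
             learning_rate, ws, nodes, li, importance, margin_update);
  build_tree(X, grad, hess, right_idx, depth + 1, max_depth, lambda, min_obs,
             learning_rate, ws, nodes, ri, importance, margin_update);
}

double tree_predict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (true) {
    const int f = (int)tree(node, 0);
    if (f < 0) return tree(node, 4);
    node = (X(row, f) < tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
}

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y,
                 int n_trees, int max_depth, double learning_rate,
                 double lambda, int min_obs, double colsample,
                 int rng_seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  // clamp so a pure class still yields a finite base margin
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double base = std::log(ybar / (1.0 - ybar));

  FitWorkspace ws;
  ws.order.resize(p);
  ws.stamp.assign(n, 0);
  for (int f = 0; f < p; ++f) {
    std::vector<int>& ord = ws.order[f];
    ord.resize(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&X, f](int a, int b) { return X(a, f) < X(b, f); });
  }

  std::vector<double> margin(n, base), grad(n), hess(n), update(n);
  std::vector<double> importance(p, 0.0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  // column subsampling: each tree sees a random feature subset (spreads
  // importance over correlated informative features); own RNG so the fit
  // depends only on (data, params, rng_seed)
  std::mt19937 rng((unsigned)rng_seed);
  std::vector<int> all_feats(p);
  for (int f = 0; f < p; ++f) all_feats[f] = f;
  const int n_keep = (colsample >= 1.0) ? p
    : std::max(1, (int)std::ceil(colsample * p));

  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    if (n_keep == p) {
      ws.features = all_feats;
    } else {
      std::shuffle(all_feats.begin(), all_feats.end(), rng);
      ws.features.assign(all_feats.begin(), all_feats.begin() + n_keep);
      std::sort(ws.features.begin(), ws.features.end());
    }
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = pr - y[i];
      hess[i] = pr * (1.0 - pr);
    }
    std::vector<Node> nodes;
    nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    std::fill(update.begin(), update.end(), 0.0);
    build_tree(X, grad, hess, all, 0, max_depth, lambda, min_obs,
               learning_rate, ws, nodes, 0, importance, update);
    for (int i = 0; i < n; ++i) margin[i] += update[i];

    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].left;
      tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[t] = tm;
  }
  return List::create(_["trees"] = trees,
                      _["base_score"] = base,
                      _["importance"] = NumericVector(importance.begin(), importance.end()),
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  List trees = model["trees"];
  const double base = as<double>(model["base_score"]);
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tm, X, i);
  }
  return out;
}
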