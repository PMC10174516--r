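// Axis-aligned classification tree used by the C4.5-style learner
// (gain-ratio splits) and as the base learner of the bagged random forest
// (gini splits with per-node feature subsampling).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids, -1 for a leaf
  std::vector<double> counts; // class counts reaching the node
};

double entropy_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double h = 0.0;
  for (double c : cnt) {
    if (c > 0) {
      double p = c / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double g = 1.0;
  for (double c : cnt) {
    double p = c / n;
    g -= p * p;
  }
  return g;
}

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double score = 0.0; // improvement; must be > 0 to split
};

// criterion: 0 = gini decrease, 1 = information gain, 2 = gain ratio
SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx,
                       const std::vector<int>& feats, int nclass,
                       int criterion, int min_leaf) {
  const int n = static_cast<int>(idx.size());
  std::vector<double> parent(nclass, 0.0);
  for (int i : idx) parent[y[i]] += 1.0;
  const double parent_imp = (criterion == 0)
    ? gini_from_counts(parent, n) : entropy_from_counts(parent, n);

  SplitResult best;
  std::vector<std::pair<double, int>> vals(n);
  std::vector<double> left(nclass);
  for (int f : feats) {
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::fill(left.begin(), left.end(), 0.0);
    double nl = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      left[vals[i].second] += 1.0;
      nl += 1.0;
      if (vals[i].first == vals[i + 1].first) continue;
      double nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double imp_l, imp_r;
      if (criterion == 0) {
        imp_l = gini_from_counts(left, nl);
        std::vector<double> right(nclass);
        for (int k = 0; k < nclass; ++k) right[k] = parent[k] - left[k];
        imp_r = gini_from_counts(right, nr);
      } else {
        imp_l = entropy_from_counts(left, nl);
        std::vector<double> right(nclass);
        for (int k = 0; k < nclass; ++k) right[k] = parent[k] - left[k];
        imp_r = entropy_from_counts(right, nr);
      }
      double child = (nl * imp_l + nr * imp_r) / n;
      double gain = parent_imp - child;
      double score = gain;
      if (criterion == 2) {
        // C4.5 gain ratio: normalize by the split information
        double pl = nl / n, pr = nr / n;
        double split_info = -(pl * std::log2(pl) + pr * std::log2(pr));
        if (split_info <= 1e-12) continue;
        score = gain / split_info;
      }
      if (score > best.score + 1e-12) {
        best.score = score;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  return best;
}

} // namespace

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int nclass,
                   int criterion, int max_depth, int min_split,
                   int min_leaf, int mtry, int seed) {
  const int p = X.ncol();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<Node> nodes;

  struct Task { std::vector<int> idx; int node_id; int depth; };
  std::vector<Task> stack;

  std::vector<int> all_rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) all_rows[i] = i;
  nodes.push_back(Node{-1, 0.0, -1, -1, {}});
  stack.push_back({all_rows, 0, 0});

  std::vector<int> all_feats(p);
  for (int f = 0; f < p; ++f) all_feats[f] = f;

  while (!stack.empty()) {
    Task task = std::move(stack.back());
    stack.pop_back();
    Node& node = nodes[task.node_id];
    node.counts.assign(nclass, 0.0);
    for (int i : task.idx) node.counts[y[i]] += 1.0;
    const int n = static_cast<int>(task.idx.size());
    bool pure = false;
    for (int k = 0; k < nclass; ++k) {
      if (node.counts[k] == static_cast<double>(n)) pure = true;
    }
    if (pure || n < min_split || task.depth >= max_depth) continue;

    std::vector<int> feats;
    if (mtry > 0 && mtry < p) {
      std::vector<int> pool = all_feats;
      std::shuffle(pool.begin(), pool.end(), rng);
      feats.assign(pool.begin(), pool.begin() + mtry);
      std::sort(feats.begin(), feats.end());
    } else {
      feats = all_feats;
    }
    SplitResult sp = best_split(X, y, task.idx, feats, nclass, criterion,
                                min_leaf);
    if (sp.feature < 0) continue;

    std::vector<int> left_idx, right_idx;
    for (int i : task.idx) {
      if (X(i, sp.feature) <= sp.threshold) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) continue;

    int lid = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0.0, -1, -1, {}});
    int rid = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0.0, -1, -1, {}});
    // re-take the reference: push_back may have reallocated
    Node& nd = nodes[task.node_id];
    nd.feature = sp.feature;
    nd.threshold = sp.threshold;
    nd.left = lid;
    nd.right = rid;
    stack.push_back({std::move(left_idx), lid, task.depth + 1});
    stack.push_back({std::move(right_idx), rid, task.depth + 1});
  }

  const int m = static_cast<int>(nodes.size());
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m);
  NumericMatrix counts(m, nclass);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    for (int k = 0; k < nclass; ++k) counts(i, k) = nodes[i].counts[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["counts"] = counts);
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericMatrix cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericMatrix counts = tree["counts"];
  const int nclass = counts.ncol();
  const int n = X.nrow();
  NumericMatrix prob(n, nclass);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    double tot = 0.0;
    for (int k = 0; k < nclass; ++k) tot += counts(node, k);
    for (int k = 0; k < nclass; ++k) prob(i, k) = counts(node, k) / tot;
  }
  return prob;
}
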