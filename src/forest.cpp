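// Small regression-forest engine used by the gradient-forest turnover
// module: depth-limited CART trees on bootstrap samples, recording every
// split (variable, split value, impurity improvement) and out-of-bag
// predictions. Deterministic for a given seed across platforms (own
// bounded-draw on top of mt19937; std::uniform_int_distribution is
// implementation-defined).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int var = -1;        // -1: leaf
  double value = 0.0;  // split threshold (go left if x <= value)
  int left = -1, right = -1;
  double pred = 0.0;
};

struct SplitRec {
  int var;
  double value;
  double gain;
};

inline uint32_t draw_below(std::mt19937& rng, uint32_t n) {
  // unbiased bounded draw
  uint32_t limit = UINT32_MAX - (UINT32_MAX % n);
  uint32_t v;
  do { v = rng(); } while (v >= limit);
  return v % n;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const NumericVector& y,
              int max_depth, int mtry, int min_node, std::mt19937& rng,
              std::vector<Node>& nodes, std::vector<SplitRec>& splits)
    : X_(X), y_(y), max_depth_(max_depth), mtry_(mtry),
      min_node_(min_node), rng_(rng), nodes_(nodes), splits_(splits) {}

  int build(std::vector<int>& idx, int depth) {
    int id = (int)nodes_.size();
    nodes_.push_back(Node());
    const int n = (int)idx.size();
    double sum = 0.0, sumsq = 0.0;
    for (int i : idx) { sum += y_[i]; sumsq += y_[i] * y_[i]; }
    const double ss_parent = sumsq - sum * sum / n;
    nodes_[id].pred = sum / n;
    if (depth >= max_depth_ || n < 2 * min_node_ || ss_parent <= 1e-12)
      return id;

    // choose mtry candidate variables without replacement
    const int p = X_.ncol();
    std::vector<int> vars(p);
    for (int j = 0; j < p; ++j) vars[j] = j;
    const int m = std::min(mtry_, p);
    for (int j = 0; j < m; ++j)
      std::swap(vars[j], vars[j + draw_below(rng_, p - j)]);

    double best_gain = 1e-12;
    int best_var = -1;
    double best_val = 0.0;
    std::vector<std::pair<double, double> > xy(n);
    for (int jj = 0; jj < m; ++jj) {
      const int v = vars[jj];
      for (int k = 0; k < n; ++k)
        xy[k] = std::make_pair(X_(idx[k], v), y_[idx[k]]);
      std::sort(xy.begin(), xy.end());
      double sl = 0.0, sql = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        sl += xy[k].second;
        sql += xy[k].second * xy[k].second;
        if (xy[k + 1].first <= xy[k].first) continue;  // no gap to split in
        const int nl = k + 1, nr = n - nl;
        if (nl < min_node_ || nr < min_node_) continue;
        const double sr = sum - sl, sqr = sumsq - sql;
        const double ssl = sql - sl * sl / nl;
        const double ssr = sqr - sr * sr / nr;
        const double gain = ss_parent - ssl - ssr;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          double mid = 0.5 * (xy[k].first + xy[k + 1].first);
          // guard against the midpoint rounding up to the right value,
          // which would empty the right child
          best_val = (mid >= xy[k + 1].first) ? xy[k].first : mid;
        }
      }
    }
    if (best_var < 0) return id;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X_(i, best_var) <= best_val) li.push_back(i);
      else ri.push_back(i);
    }
    SplitRec rec; rec.var = best_var; rec.value = best_val;
    rec.gain = best_gain;
    splits_.push_back(rec);
    nodes_[id].var = best_var;
    nodes_[id].value = best_val;
    nodes_[id].left = build(li, depth + 1);
    nodes_[id].right = build(ri, depth + 1);
    return id;
  }

private:
  const NumericMatrix& X_;
  const NumericVector& y_;
  int max_depth_, mtry_, min_node_;
  std::mt19937& rng_;
  std::vector<Node>& nodes_;
  std::vector<SplitRec>& splits_;
};

double predict_tree(const std::vector<Node>& nodes, const NumericMatrix& X,
                    int row) {
  int id = 0;
  while (nodes[id].var >= 0)
    id = (X(row, nodes[id].var) <= nodes[id].value)
       ? nodes[id].left : nodes[id].right;
  return nodes[id].pred;
}

}  // namespace

// [[Rcpp::export(name = ".fit_regression_forest")]]
List fit_regression_forest(NumericMatrix X, NumericVector y,
                           int ntree, int max_depth, int mtry,
                           int min_node, int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y dimensions disagree");
  if (ntree < 1) stop("ntree must be >= 1");
  std::mt19937 rng((uint32_t)seed);

  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_count(n, 0);
  std::vector<SplitRec> splits;
  std::vector<char> inbag(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = (int)draw_below(rng, n);
      inbag[idx[i]] = 1;
    }
    std::vector<Node> nodes;
    TreeBuilder tb(X, y, max_depth, mtry, min_node, rng, nodes, splits);
    tb.build(idx, 0);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_tree(nodes, X, i);
        oob_count[i] += 1;
      }
    }
  }

  const int ns = (int)splits.size();
  IntegerVector s_var(ns);
  NumericVector s_val(ns), s_gain(ns);
  for (int k = 0; k < ns; ++k) {
    s_var[k] = splits[k].var + 1;  // 1-based for R
    s_val[k] = splits[k].value;
    s_gain[k] = splits[k].gain;
  }
  return List::create(
    _["oob_sum"] = oob_sum,
    _["oob_count"] = oob_count,
    _["split_var"] = s_var,
    _["split_value"] = s_val,
    _["split_gain"] = s_gain
  );
}
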