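// Regression random forest (CART trees, variance-reduction splits,
// bootstrap resampling, OOB tracking).  Self-contained so the package
// does not depend on an external forest implementation; the RNG is a
// seeded mt19937 independent of R's RNG stream, which makes fits
// bit-reproducible for a given seed regardless of the caller's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left if x <= threshold
  int left;
  int right;
  double value;     // leaf prediction (node mean)
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// Best variance-reduction split over `mtry` candidate features for the
// samples idx[lo..hi).  Gain is the decrease in total SSE.
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& idx, int lo, int hi,
                       int mtry, std::mt19937& rng,
                       std::vector<int>& feat_pool,
                       std::vector<std::pair<double, double>>& buf) {
  const int m = hi - lo;
  const int p = X.ncol();
  SplitResult best;

  double sum_all = 0.0, ss_all = 0.0;
  for (int k = lo; k < hi; ++k) {
    const double v = y[idx[k]];
    sum_all += v;
    ss_all += v * v;
  }
  const double sse_parent = ss_all - sum_all * sum_all / m;

  // partial Fisher-Yates to draw mtry features without replacement
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  const int draw = std::min(mtry, p);
  for (int d = 0; d < draw; ++d) {
    std::uniform_int_distribution<int> pick(d, p - 1);
    std::swap(feat_pool[d], feat_pool[pick(rng)]);
    const int f = feat_pool[d];

    buf.clear();
    for (int k = lo; k < hi; ++k)
      buf.emplace_back(X(idx[k], f), y[idx[k]]);
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue; // constant feature

    double sum_left = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      sum_left += buf[k].second;
      if (buf[k].first == buf[k + 1].first) continue;
      const int nl = k + 1, nr = m - nl;
      const double sum_right = sum_all - sum_left;
      const double gain = sum_left * sum_left / nl +
                          sum_right * sum_right / nr -
                          sum_all * sum_all / m;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = (buf[k].first + buf[k + 1].first) / 2.0;
      }
    }
  }
  if (best.feature >= 0 && best.gain <= 1e-10 * std::max(1.0, sse_parent))
    best.feature = -1; // numerically null gain: make a leaf
  return best;
}

void grow_node(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int lo, int hi,
               std::vector<Node>& nodes, int node_id,
               int mtry, int min_node, int depth, int max_depth,
               std::mt19937& rng,
               std::vector<int>& feat_pool,
               std::vector<std::pair<double, double>>& buf) {
  const int m = hi - lo;
  double mean = 0.0;
  for (int k = lo; k < hi; ++k) mean += y[idx[k]];
  mean /= m;
  nodes[node_id].value = mean;
  nodes[node_id].feature = -1;

  if (m <= min_node || depth >= max_depth) return;

  SplitResult sp = best_split(X, y, idx, lo, hi, mtry, rng, feat_pool, buf);
  if (sp.feature < 0) return;

  // partition idx[lo..hi) in place
  int i = lo, j = hi - 1;
  while (i <= j) {
    if (X(idx[i], sp.feature) <= sp.threshold) {
      ++i;
    } else {
      std::swap(idx[i], idx[j]);
      --j;
    }
  }
  const int mid = i;
  if (mid == lo || mid == hi) return; // degenerate, keep leaf

  const int left_id = (int)nodes.size();
  nodes.push_back(Node());
  const int right_id = (int)nodes.size();
  nodes.push_back(Node());
  nodes[node_id].feature = sp.feature;
  nodes[node_id].threshold = sp.threshold;
  nodes[node_id].left = left_id;
  nodes[node_id].right = right_id;

  grow_node(X, y, idx, lo, mid, nodes, left_id, mtry, min_node,
            depth + 1, max_depth, rng, feat_pool, buf);
  grow_node(X, y, idx, mid, hi, nodes, right_id, mtry, min_node,
            depth + 1, max_depth, rng, feat_pool, buf);
}

double predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_count(n, 0);
  std::vector<int> idx;
  std::vector<char> inbag(n);
  std::vector<int> feat_pool(p);
  std::vector<std::pair<double, double>> buf;
  buf.reserve(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.resize(n);
    for (int k = 0; k < n; ++k) {
      const int s = boot(rng);
      idx[k] = s;
      inbag[s] = 1;
    }
    std::vector<Node> nodes(1);
    grow_node(X, y, idx, 0, n, nodes, 0, mtry, min_node, 0, max_depth,
              rng, feat_pool, buf);

    NumericMatrix tm((int)nodes.size(), 5);
    for (int k = 0; k < (int)nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].left;
      tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[t] = tm;

    for (int r = 0; r < n; ++r) {
      if (!inbag[r]) {
        oob_sum[r] += predict_one(tm, X, r);
        oob_count[r] += 1;
      }
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int r = 0; r < n; ++r)
    if (oob_count[r] > 0) oob_pred[r] = oob_sum[r] / oob_count[r];

  return List::create(_["trees"] = trees, _["oob_pred"] = oob_pred);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int r = 0; r < n; ++r) out[r] += predict_one(tm, X, r);
  }
  for (int r = 0; r < n; ++r) out[r] /= ntree;
  return out;
}
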