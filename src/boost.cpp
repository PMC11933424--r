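// Regression-tree primitives for the multiclass gradient booster.
// Exact greedy split search with second-order (gradient/hessian) statistics:
// leaf value -G/(H+lambda); split gain 0.5*(GL^2/(HL+l)+GR^2/(HR+l)-G^2/(H+l))
// minus the minimum-loss-reduction penalty gamma. A split is also rejected
// when either child's hessian mass falls below min_child_weight. Row and
// column subsampling are decided by the R driver (which owns the RNG) and
// passed in as index vectors, so training is deterministic given a seed.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;     // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;   // leaf weight
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& grad;
  const NumericVector& hess;
  const IntegerVector& cols;  // 0-based candidate features for this tree
  int max_depth;
  double min_child_weight, gamma, lambda;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const NumericVector& g,
          const NumericVector& h, const IntegerVector& cols_, int md,
          double mcw, double gma, double lam)
      : X(X_), grad(g), hess(h), cols(cols_), max_depth(md),
        min_child_weight(mcw), gamma(gma), lambda(lam) {}

  int build(std::vector<int>& rows, int depth) {
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += grad[r]; H += hess[r]; }

    int best_feat = -1;
    double best_thr = 0.0, best_gain = 0.0;
    if (depth < max_depth && rows.size() >= 2) {
      const double parent_score = G * G / (H + lambda);
      std::vector<std::pair<double, int> > vals;
      vals.reserve(rows.size());
      for (int ci = 0; ci < cols.size(); ++ci) {
        const int f = cols[ci];
        vals.clear();
        for (int r : rows) vals.push_back(std::make_pair(X(r, f), r));
        std::sort(vals.begin(), vals.end());
        double GL = 0.0, HL = 0.0;
        for (size_t i = 0; i + 1 < vals.size(); ++i) {
          const int r = vals[i].second;
          GL += grad[r]; HL += hess[r];
          if (vals[i].first == vals[i + 1].first) continue;
          const double HR = H - HL, GR = G - GL;
          if (HL < min_child_weight || HR < min_child_weight) continue;
          const double gain =
              0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                     parent_score) - gamma;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }

    const int id = (int)nodes.size();
    nodes.push_back(Node());
    if (best_feat < 0) {
      nodes[id].value = -G / (H + lambda);
      return id;
    }
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, best_feat) < best_thr) lrows.push_back(r);
      else rrows.push_back(r);
    }
    rows.clear(); rows.shrink_to_fit();
    nodes[id].feature = best_feat;
    nodes[id].threshold = best_thr;
    const int l = build(lrows, depth + 1);
    const int r = build(rrows, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector grad, NumericVector hess,
                  IntegerVector rows, IntegerVector cols, int max_depth,
                  double min_child_weight, double gamma, double lambda) {
  Builder b(X, grad, hess, cols, max_depth, min_child_weight, gamma, lambda);
  std::vector<int> rvec(rows.begin(), rows.end());
  b.build(rvec, 0);
  const int n = (int)b.nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = b.nodes[i].feature;
    threshold[i] = b.nodes[i].threshold;
    left[i] = b.nodes[i].left;
    right[i] = b.nodes[i].right;
    value[i] = b.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) < threshold[node]) ? left[node]
                                                     : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
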