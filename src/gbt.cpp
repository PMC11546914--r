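#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Gradient-boosted decision trees for binary classification, XGBoost-style:
// second-order logistic loss, exact greedy split search, L2 leaf
// regularisation. Deterministic: no subsampling, no RNG; split ties resolved
// by lowest feature index then lowest threshold.

namespace {

struct TreeNode {
  bool leaf;
  int feat;
  double thr;
  double w;
  int left, right;
};

struct SplitResult {
  double gain;
  int feat;
  double thr;
};

void build_node(const NumericMatrix& X,
                const std::vector<double>& g,
                const std::vector<double>& h,
                std::vector<int>& idx,
                int depth, int max_depth,
                double lambda, double gamma, double min_child_weight,
                std::vector<TreeNode>& nodes, int node_id) {
  const int n = static_cast<int>(idx.size());
  double G = 0.0, H = 0.0;
  for (int i = 0; i < n; ++i) { G += g[idx[i]]; H += h[idx[i]]; }

  nodes[node_id].leaf = true;
  nodes[node_id].w = -G / (H + lambda);
  nodes[node_id].left = nodes[node_id].right = -1;
  if (depth >= max_depth || n < 2) return;

  const double parent_score = G * G / (H + lambda);
  SplitResult best{0.0, -1, 0.0};

  const int p = X.ncol();
  std::vector<std::pair<double, int> > ord(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = std::make_pair(X(idx[i], j), idx[i]);
    std::stable_sort(ord.begin(), ord.end());
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      GL += g[ord[i].second];
      HL += h[ord[i].second];
      if (ord[i].first == ord[i + 1].first) continue;  // no cut between ties
      const double HR = H - HL, GR = G - GL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      const double gain =
          0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                 parent_score) - gamma;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feat = j;
        best.thr = 0.5 * (ord[i].first + ord[i + 1].first);
      }
    }
  }
  if (best.feat < 0) return;  // no positive-gain split: stay a leaf

  std::vector<int> lidx, ridx;
  lidx.reserve(n); ridx.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], best.feat) < best.thr) lidx.push_back(idx[i]);
    else ridx.push_back(idx[i]);
  }
  if (lidx.empty() || ridx.empty()) return;

  // nodes may reallocate on push_back: never hold a reference across it
  const int left_id = static_cast<int>(nodes.size());
  const int right_id = left_id + 1;
  nodes.push_back(TreeNode());
  nodes.push_back(TreeNode());
  nodes[node_id].leaf = false;
  nodes[node_id].feat = best.feat;
  nodes[node_id].thr = best.thr;
  nodes[node_id].left = left_id;
  nodes[node_id].right = right_id;
  build_node(X, g, h, lidx, depth + 1, max_depth, lambda, gamma,
             min_child_weight, nodes, left_id);
  build_node(X, g, h, ridx, depth + 1, max_depth, lambda, gamma,
             min_child_weight, nodes, right_id);
}

double tree_predict(const std::vector<TreeNode>& nodes,
                    const NumericMatrix& X, int row) {
  int cur = 0;
  while (!nodes[cur].leaf)
    cur = (X(row, nodes[cur].feat) < nodes[cur].thr) ? nodes[cur].left
                                                     : nodes[cur].right;
  return nodes[cur].w;
}

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".gbt_train_predict")]]
NumericVector gbt_train_predict(NumericMatrix Xtr, IntegerVector ytr,
                                NumericMatrix Xte, int nrounds, double eta,
                                int max_depth, double lambda,
                                double min_child_weight, double gamma,
                                double base_score) {
  const int ntr = Xtr.nrow(), nte = Xte.nrow();
  if (ytr.size() != ntr) stop("length(y) must match nrow(Xtr)");
  const double base_margin = std::log(base_score / (1.0 - base_score));
  std::vector<double> mtr(ntr, base_margin), mte(nte, base_margin);
  std::vector<double> g(ntr), h(ntr);
  std::vector<int> all(ntr);
  for (int i = 0; i < ntr; ++i) all[i] = i;

  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < ntr; ++i) {
      const double p = sigmoid(mtr[i]);
      g[i] = p - ytr[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    std::vector<TreeNode> nodes(1);
    std::vector<int> idx(all);
    build_node(Xtr, g, h, idx, 0, max_depth, lambda, gamma, min_child_weight,
               nodes, 0);
    for (int i = 0; i < ntr; ++i) mtr[i] += eta * tree_predict(nodes, Xtr, i);
    for (int i = 0; i < nte; ++i) mte[i] += eta * tree_predict(nodes, Xte, i);
  }

  NumericVector out(nte);
  for (int i = 0; i < nte; ++i) out[i] = sigmoid(mte[i]);
  return out;
}
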