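// Random forest of CART trees for binary classification.
//
// Trees are exchanged with R as plain parallel-array tables (var, val,
// left, right, pred, n0, n1) so models can be serialized to text and
// hand-built in tests; the Boruta loop uses a fused native entry point
// (cpp_boruta_importance) that avoids marshalling. Class codes:
// 0 = non_sensitive, 1 = sensitive. Vote ties resolve to class 0 at the
// R level (the fraction is returned here).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeN {
  std::vector<int> var;      // split feature (0-based), -1 for leaf
  std::vector<double> val;   // split threshold (go left if x <= val)
  std::vector<int> left, right;  // child node index, -1 for leaf
  std::vector<int> pred;     // majority class at node (tie -> 0)
  std::vector<int> n0, n1;   // class counts of training samples at node
};

struct ForestN {
  std::vector<TreeN> trees;
  std::vector<std::vector<int>> oob;  // 0-based sample indices
  int bootstrap_size = 0;
};

// Reusable per-forest scratch buffers.
struct Work {
  std::vector<double> vals, vals2;
  std::vector<int> labs, order, feats, samples;
};

// Weighted Gini cost of a node, 0 when pure.
inline double gini_cost(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  return n - (c0 * c0 + c1 * c1) / n;
}

struct NodeTask {
  int node, start, end;
};

void train_tree(const double* X, int N, int p, const int* y, int mtry,
                int min_leaf, std::mt19937& rng, TreeN& tr, Work& w) {
  if ((int)w.feats.size() != p) {
    w.feats.resize(p);
    for (int j = 0; j < p; ++j) w.feats[j] = j;
  }
  std::vector<NodeTask> stack;
  auto new_node = [&tr]() {
    tr.var.push_back(-1);
    tr.val.push_back(0.0);
    tr.left.push_back(-1);
    tr.right.push_back(-1);
    tr.pred.push_back(0);
    tr.n0.push_back(0);
    tr.n1.push_back(0);
    return (int)tr.var.size() - 1;
  };
  stack.push_back({new_node(), 0, (int)w.samples.size()});

  while (!stack.empty()) {
    NodeTask task = stack.back();
    stack.pop_back();
    const int s = task.end - task.start;
    int* smp = w.samples.data() + task.start;
    int c0 = 0, c1 = 0;
    for (int k = 0; k < s; ++k) (y[smp[k]] == 0 ? ++c0 : ++c1);
    tr.n0[task.node] = c0;
    tr.n1[task.node] = c1;
    tr.pred[task.node] = (c1 > c0) ? 1 : 0;
    if (c0 == 0 || c1 == 0 || s < 2 * min_leaf) continue;

    const double parent_cost = gini_cost(c0, c1);
    double best_cost = parent_cost;
    int best_var = -1;
    double best_val = 0.0;

    // sample mtry distinct features (partial Fisher-Yates)
    const int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(w.feats[j], w.feats[pick(rng)]);
    }
    if ((int)w.vals.size() < s) {
      w.vals.resize(s);
      w.vals2.resize(s);
      w.labs.resize(s);
      w.order.resize(s);
    }
    for (int jj = 0; jj < m; ++jj) {
      const int f = w.feats[jj];
      const double* col = X + (size_t)f * N;
      // node samples sorted by feature f, gathered into local buffers
      if (s <= 24) {  // insertion sort: small nodes dominate deep trees
        for (int k = 0; k < s; ++k) {
          const double vk = col[smp[k]];
          const int lk = y[smp[k]];
          int j2 = k - 1;
          while (j2 >= 0 && w.vals[j2] > vk) {
            w.vals[j2 + 1] = w.vals[j2];
            w.labs[j2 + 1] = w.labs[j2];
            --j2;
          }
          w.vals[j2 + 1] = vk;
          w.labs[j2 + 1] = lk;
        }
      } else {
        for (int k = 0; k < s; ++k) {
          w.vals[k] = col[smp[k]];
          w.order[k] = k;
        }
        const double* vp = w.vals.data();
        std::sort(w.order.begin(), w.order.begin() + s,
                  [vp](int a, int b) { return vp[a] < vp[b]; });
        for (int k = 0; k < s; ++k) {
          const int o = w.order[k];
          w.vals2[k] = w.vals[o];
          w.labs[k] = y[smp[o]];
        }
        std::swap(w.vals, w.vals2);
      }
      if (w.vals[0] == w.vals[s - 1]) continue;  // constant feature
      double c0l = 0.0, c1l = 0.0;
      for (int k = 0; k < s - 1; ++k) {
        (w.labs[k] == 0 ? c0l : c1l) += 1.0;
        const double a = w.vals[k], b = w.vals[k + 1];
        if (a == b) continue;
        const int nl = k + 1, nr = s - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const double cost = gini_cost(c0l, c1l) + gini_cost(c0 - c0l, c1 - c1l);
        if (cost < best_cost - 1e-12) {
          best_cost = cost;
          best_var = f;
          best_val = a + (b - a) / 2.0;
        }
      }
      if (best_cost <= 1e-12) break;  // perfect split found
    }
    if (best_var < 0) continue;

    // in-place partition: left block first
    const double* col = X + (size_t)best_var * N;
    int lo = task.start, hi = task.end - 1;
    while (lo <= hi) {
      if (col[w.samples[lo]] <= best_val) {
        ++lo;
      } else {
        std::swap(w.samples[lo], w.samples[hi]);
        --hi;
      }
    }
    const int mid = lo;
    tr.var[task.node] = best_var;
    tr.val[task.node] = best_val;
    const int lnode = new_node();
    const int rnode = new_node();
    tr.left[task.node] = lnode;
    tr.right[task.node] = rnode;
    stack.push_back({lnode, task.start, mid});
    stack.push_back({rnode, mid, task.end});
  }
}

ForestN train_forest_native(const double* X, int N, int p, const int* y,
                            int n_trees, int mtry, double sample_frac,
                            bool replace, int min_leaf, unsigned seed) {
  const int m = (int)std::ceil(sample_frac * N);
  std::mt19937 rng(seed);
  ForestN fo;
  fo.bootstrap_size = m;
  fo.trees.resize(n_trees);
  fo.oob.resize(n_trees);
  Work w;
  std::vector<int> pool(N);
  std::vector<char> used(N);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(used.begin(), used.end(), 0);
    w.samples.clear();
    w.samples.reserve(m);
    if (replace) {
      std::uniform_int_distribution<int> pick(0, N - 1);
      for (int s = 0; s < m; ++s) {
        int i = pick(rng);
        w.samples.push_back(i);
        used[i] = 1;
      }
    } else {
      for (int i = 0; i < N; ++i) pool[i] = i;
      for (int s = 0; s < m; ++s) {
        std::uniform_int_distribution<int> pick(s, N - 1);
        std::swap(pool[s], pool[pick(rng)]);
        w.samples.push_back(pool[s]);
        used[pool[s]] = 1;
      }
    }
    for (int i = 0; i < N; ++i)
      if (!used[i]) fo.oob[t].push_back(i);
    train_tree(X, N, p, y, mtry, min_leaf, rng, fo.trees[t], w);
  }
  return fo;
}

inline int predict_one(const TreeN& tr, const double* X, int N, int i) {
  int node = 0;
  while (tr.var[node] >= 0) {
    node = (X[(size_t)tr.var[node] * N + i] <= tr.val[node]) ? tr.left[node]
                                                             : tr.right[node];
  }
  return tr.pred[node];
}

// Descend with one feature's values read through a row permutation.
inline int predict_one_permuted(const TreeN& tr, const double* X, int N,
                                int i, int pf, const int* perm) {
  int node = 0;
  while (tr.var[node] >= 0) {
    const int v = tr.var[node];
    const int row = (v == pf) ? perm[i] : i;
    node = (X[(size_t)v * N + row] <= tr.val[node]) ? tr.left[node]
                                                    : tr.right[node];
  }
  return tr.pred[node];
}

// Permutation importance on out-of-bag samples. For feature j: one row
// permutation, then per tree the OOB accuracy before minus after reading
// j through the permutation; trees that never split on j lose exactly 0.
// MDA = mean per-tree loss over trees with nonempty OOB sets,
// Z = MDA / sd(losses), 0 when the sd is 0.
void importance_native(const ForestN& fo, const double* X, int N, int p,
                       const int* y, unsigned seed, double* mda, double* sdv,
                       double* zsc) {
  const int T = (int)fo.trees.size();
  std::mt19937 rng(seed);

  std::vector<int> live;
  std::vector<double> acc0(T, 0.0);
  for (int t = 0; t < T; ++t) {
    if (fo.oob[t].empty()) continue;
    int ok = 0;
    for (int i : fo.oob[t]) ok += (predict_one(fo.trees[t], X, N, i) == y[i]);
    acc0[t] = (double)ok / (double)fo.oob[t].size();
    live.push_back(t);
  }
  const int L = (int)live.size();

  // trees (by live index) using each feature
  std::vector<std::vector<int>> users(p);
  std::vector<char> seen(p);
  for (int lt = 0; lt < L; ++lt) {
    const TreeN& tr = fo.trees[live[lt]];
    std::fill(seen.begin(), seen.end(), 0);
    for (int v : tr.var)
      if (v >= 0 && !seen[v]) {
        seen[v] = 1;
        users[v].push_back(lt);
      }
  }

  std::vector<int> perm(N);
  std::vector<double> loss(L);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < N; ++i) perm[i] = i;
    std::shuffle(perm.begin(), perm.end(), rng);
    std::fill(loss.begin(), loss.end(), 0.0);
    for (int lt : users[j]) {
      const int t = live[lt];
      int ok = 0;
      for (int i : fo.oob[t])
        ok += (predict_one_permuted(fo.trees[t], X, N, i, j, perm.data()) ==
               y[i]);
      loss[lt] = acc0[t] - (double)ok / (double)fo.oob[t].size();
    }
    double mean = 0.0;
    for (double l : loss) mean += l;
    mean /= (double)L;
    double ss = 0.0;
    for (double l : loss) ss += (l - mean) * (l - mean);
    const double sd = (L > 1) ? std::sqrt(ss / (double)(L - 1)) : 0.0;
    mda[j] = mean;
    sdv[j] = sd;
    zsc[j] = (sd > 0.0) ? mean / sd : 0.0;
  }
}

List forest_to_list(const ForestN& fo) {
  const int T = (int)fo.trees.size();
  List trees(T), oob(T);
  for (int t = 0; t < T; ++t) {
    const TreeN& tr = fo.trees[t];
    trees[t] = List::create(
        _["var"] = IntegerVector(tr.var.begin(), tr.var.end()),
        _["val"] = NumericVector(tr.val.begin(), tr.val.end()),
        _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
        _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
        _["pred"] = IntegerVector(tr.pred.begin(), tr.pred.end()),
        _["n0"] = IntegerVector(tr.n0.begin(), tr.n0.end()),
        _["n1"] = IntegerVector(tr.n1.begin(), tr.n1.end()));
    std::vector<int> o1(fo.oob[t]);
    for (int& i : o1) ++i;  // 1-based for R
    oob[t] = IntegerVector(o1.begin(), o1.end());
  }
  return List::create(_["trees"] = trees, _["oob"] = oob,
                      _["bootstrap_size"] = fo.bootstrap_size);
}

TreeN tree_from_list(const List& tl) {
  TreeN tr;
  IntegerVector var = tl["var"], left = tl["left"], right = tl["right"],
                pred = tl["pred"], n0 = tl["n0"], n1 = tl["n1"];
  NumericVector val = tl["val"];
  tr.var.assign(var.begin(), var.end());
  tr.val.assign(val.begin(), val.end());
  tr.left.assign(left.begin(), left.end());
  tr.right.assign(right.begin(), right.end());
  tr.pred.assign(pred.begin(), pred.end());
  tr.n0.assign(n0.begin(), n0.end());
  tr.n1.assign(n1.begin(), n1.end());
  return tr;
}

ForestN forest_from_lists(const List& trees, const List& oob) {
  ForestN fo;
  fo.trees.reserve(trees.size());
  for (int t = 0; t < trees.size(); ++t)
    fo.trees.push_back(tree_from_list(trees[t]));
  fo.oob.resize(oob.size());
  for (int t = 0; t < oob.size(); ++t) {
    IntegerVector o = oob[t];
    fo.oob[t].reserve(o.size());
    for (int k = 0; k < o.size(); ++k) fo.oob[t].push_back(o[k] - 1);
  }
  return fo;
}

}  // namespace

// [[Rcpp::export]]
List cpp_train_forest(NumericMatrix X, IntegerVector y, int n_trees,
                      int mtry, double sample_frac, bool replace,
                      int min_leaf, int seed) {
  ForestN fo = train_forest_native(REAL(X), X.nrow(), X.ncol(),
                                   INTEGER(y), n_trees, mtry, sample_frac,
                                   replace, min_leaf, (unsigned)seed);
  return forest_to_list(fo);
}

// Fraction of trees voting class 1 ("sensitive") for each row of X.
// [[Rcpp::export]]
NumericVector cpp_forest_vote(List trees, NumericMatrix X) {
  const int N = X.nrow(), T = trees.size();
  const double* Xp = REAL(X);
  NumericVector frac(N);
  for (int t = 0; t < T; ++t) {
    TreeN tr = tree_from_list(trees[t]);
    for (int i = 0; i < N; ++i) frac[i] += predict_one(tr, Xp, N, i);
  }
  for (int i = 0; i < N; ++i) frac[i] /= (double)T;
  return frac;
}

// Per-tree predictions (rows = samples, cols = trees), class codes 0/1.
// [[Rcpp::export]]
IntegerMatrix cpp_forest_predict_all(List trees, NumericMatrix X) {
  const int N = X.nrow(), T = trees.size();
  const double* Xp = REAL(X);
  IntegerMatrix out(N, T);
  for (int t = 0; t < T; ++t) {
    TreeN tr = tree_from_list(trees[t]);
    for (int i = 0; i < N; ++i) out(i, t) = predict_one(tr, Xp, N, i);
  }
  return out;
}

// Permutation importance for an already-trained (possibly hand-built)
// forest held as R tree tables.
// [[Rcpp::export]]
List cpp_forest_importance(List trees, List oob, NumericMatrix X,
                           IntegerVector y, int seed) {
  ForestN fo = forest_from_lists(trees, oob);
  const int p = X.ncol();
  NumericVector mda(p), sdv(p), zsc(p);
  importance_native(fo, REAL(X), X.nrow(), p, INTEGER(y), (unsigned)seed,
                    REAL(mda), REAL(sdv), REAL(zsc));
  return List::create(_["mda"] = mda, _["sd"] = sdv, _["z"] = zsc);
}

// Fused train + permutation importance (one Boruta iteration's forest),
// skipping the R-level tree representation entirely.
// [[Rcpp::export]]
List cpp_boruta_importance(NumericMatrix X, IntegerVector y, int n_trees,
                           int mtry, double sample_frac, bool replace,
                           int min_leaf, int seed_forest, int seed_perm) {
  ForestN fo = train_forest_native(REAL(X), X.nrow(), X.ncol(),
                                   INTEGER(y), n_trees, mtry, sample_frac,
                                   replace, min_leaf, (unsigned)seed_forest);
  const int p = X.ncol();
  NumericVector mda(p), sdv(p), zsc(p);
  importance_native(fo, REAL(X), X.nrow(), p, INTEGER(y),
                    (unsigned)seed_perm, REAL(mda), REAL(sdv), REAL(zsc));
  return List::create(_["mda"] = mda, _["sd"] = sdv, _["z"] = zsc);
}
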