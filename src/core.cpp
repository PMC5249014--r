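#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Nucleotide codes: 0 = A, 1 = C, 2 = G, 3 = U.
static inline bool comp_nt(int a, int b) {
  if (a > b) std::swap(a, b);
  return (a == 0 && b == 3) ||  // A:U
         (a == 1 && b == 2) ||  // C:G
         (a == 2 && b == 3);    // G:U wobble
}

// Per-pair energy of the stacking-count approximation (kcal/mol).
static inline double pair_energy(int a, int b) {
  if (a > b) std::swap(a, b);
  if (a == 1 && b == 2) return -2.0;
  if (a == 0 && b == 3) return -1.0;
  if (a == 2 && b == 3) return -0.5;
  return 0.0;
}

// [[Rcpp::export]]
LogicalMatrix cpp_complement_pairs(IntegerVector a, IntegerVector b) {
  LogicalMatrix out(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i)
    for (int j = 0; j < b.size(); ++j)
      out(i, j) = comp_nt(a[i], b[j]);
  return out;
}

// Triangular base-pairing matrix. Column j holds s[j], row i holds
// s[n-1-i]; cell (i,j) is 0 when the two bases cannot pair, otherwise
// one more than the up-left neighbour, so positive values measure the
// contiguous paired run ending at the cell along its diagonal.
// The companion matrix `inward` counts the run continuing down-right,
// i.e. toward the terminal loop, used by the stage-3 extension search.
// [[Rcpp::export]]
List cpp_pairing_runs(IntegerVector s) {
  const int n = s.size();
  IntegerMatrix run(n, n), inward(n, n);
  for (int i = 0; i < n; ++i) {
    const int ri = s[n - 1 - i];
    for (int j = 0; j < n; ++j) {
      if (comp_nt(s[j], ri))
        run(i, j) = (i > 0 && j > 0) ? run(i - 1, j - 1) + 1 : 1;
      else
        run(i, j) = 0;
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    const int ri = s[n - 1 - i];
    for (int j = n - 1; j >= 0; --j) {
      if (comp_nt(s[j], ri))
        inward(i, j) = (i < n - 1 && j < n - 1) ? inward(i + 1, j + 1) + 1 : 1;
      else
        inward(i, j) = 0;
    }
  }
  return List::create(_["run"] = run, _["inward"] = inward);
}

// Minimum free energy of the best nested structure under the per-pair
// stacking-count approximation (GC -2, AU -1, GU -0.5 kcal/mol), with a
// minimum hairpin loop of `min_loop` unpaired nt. Standard O(n^3)
// maximum-weight nested pairing recursion.
// [[Rcpp::export]]
double cpp_fold_mfe(IntegerVector s, int min_loop) {
  const int n = s.size();
  if (n < 2) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      double best = E[(size_t)(i + 1) * n + j];               // i unpaired
      best = std::min(best, E[(size_t)i * n + (j - 1)]);      // j unpaired
      if (comp_nt(s[i], s[j]))
        best = std::min(best, ((i + 1 <= j - 1)
                                 ? E[(size_t)(i + 1) * n + (j - 1)]
                                 : 0.0) + pair_energy(s[i], s[j]));
      for (int k = i; k < j; ++k)                             // bifurcation
        best = std::min(best, E[(size_t)i * n + k] +
                              E[(size_t)(k + 1) * n + j]);
      E[(size_t)i * n + j] = best;
    }
  }
  return E[(size_t)0 * n + (n - 1)];
}

// Maximal runs of pairable positions on the diagonal with pair sum S of
// an n x n run matrix, restricted to the triangle where the arms are
// separated by >= min_loop nt. Returns a 2-column matrix (a0, L).
// [[Rcpp::export]]
IntegerMatrix cpp_diag_runs(const IntegerMatrix &run, int S, int min_loop) {
  const int n = run.nrow();
  const int a_min = std::max(0, S - (n - 1));
  const int a_max = (S - min_loop - 1) / 2;
  std::vector<int> a0s, Ls;
  int cur_start = -1;
  for (int a = a_min; a <= a_max; ++a) {
    const int i = n - 1 - (S - a);
    const bool ok = run(i, a) > 0;
    if (ok && cur_start < 0) cur_start = a;
    if (!ok && cur_start >= 0) {
      a0s.push_back(cur_start);
      Ls.push_back(a - cur_start);
      cur_start = -1;
    }
  }
  if (cur_start >= 0) {
    a0s.push_back(cur_start);
    Ls.push_back(a_max + 1 - cur_start);
  }
  IntegerMatrix out((int)a0s.size(), 2);
  for (int k = 0; k < (int)a0s.size(); ++k) {
    out(k, 0) = a0s[k];
    out(k, 1) = Ls[k];
  }
  colnames(out) = CharacterVector::create("a0", "L");
  return out;
}

// All exact stems (maximal diagonal runs of length >= min_len inside the
// valid triangle) as a 3-column matrix (psum, a0, L), ordered by
// diagonal id (n-1-psum) then 5' start.
// [[Rcpp::export]]
IntegerMatrix cpp_all_stems(const IntegerMatrix &run, int min_len,
                            int min_loop) {
  const int n = run.nrow();
  std::vector<int> Ss, a0s, Ls;
  for (int S = 2 * n - 3; S >= 1; --S) {  // diag = n-1-S ascending
    const int a_min = std::max(0, S - (n - 1));
    const int a_max = (S - min_loop - 1) / 2;
    int cur_start = -1;
    for (int a = a_min; a <= a_max + 1; ++a) {
      const bool ok = a <= a_max &&
        run(n - 1 - (S - a), a) > 0;
      if (ok && cur_start < 0) cur_start = a;
      if (!ok && cur_start >= 0) {
        if (a - cur_start >= min_len) {
          Ss.push_back(S);
          a0s.push_back(cur_start);
          Ls.push_back(a - cur_start);
        }
        cur_start = -1;
      }
    }
  }
  IntegerMatrix out((int)Ss.size(), 3);
  for (int k = 0; k < (int)Ss.size(); ++k) {
    out(k, 0) = Ss[k];
    out(k, 1) = a0s[k];
    out(k, 2) = Ls[k];
  }
  colnames(out) = CharacterVector::create("psum", "a0", "L");
  return out;
}

// ---------------------------------------------------------------------------
// Random forest: bootstrap-bagged CART with per-split random feature
// subsets. Self-contained xorshift RNG so that training is reproducible
// across platforms for a given integer seed.
// ---------------------------------------------------------------------------

struct XorShift {
  uint64_t state;
  explicit XorShift(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x << 13; x ^= x >> 7; x ^= x << 17;
    return state = x;
  }
  // uniform integer in [0, m)
  int unif_int(int m) { return (int)(next() % (uint64_t)m); }
  double unif01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct TreeNode {
  int feature;     // -1 for leaf
  double thresh;
  int left, right; // node indices
  double prob;     // P(class 1) at leaf
};

static double gini_impurity(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

static void build_node(const NumericMatrix &X, const IntegerVector &y,
                       std::vector<int> &idx, int lo, int hi, int depth,
                       int mtry, int min_node, int max_depth, XorShift &rng,
                       std::vector<TreeNode> &nodes, int node_id) {
  const int n = hi - lo;
  int n1 = 0;
  for (int t = lo; t < hi; ++t) n1 += y[idx[t]];
  nodes[node_id].prob = n > 0 ? (double)n1 / n : 0.5;
  nodes[node_id].feature = -1;
  if (n < min_node || n1 == 0 || n1 == n || depth >= max_depth) return;

  const int p = X.ncol();
  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  for (int f = 0; f < mtry && f < p; ++f)
    std::swap(feats[f], feats[f + rng.unif_int(p - f)]);

  double best_score = gini_impurity(n1, n);
  int best_f = -1;
  double best_thresh = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int fi = 0; fi < mtry && fi < p; ++fi) {
    const int f = feats[fi];
    for (int t = 0; t < n; ++t)
      vals[t] = std::make_pair(X(idx[lo + t], f), y[idx[lo + t]]);
    std::sort(vals.begin(), vals.end());
    int left1 = 0;
    for (int t = 0; t < n - 1; ++t) {
      left1 += vals[t].second;
      if (vals[t].first == vals[t + 1].first) continue;
      const int nl = t + 1, nr = n - nl;
      double score = (nl * gini_impurity(left1, nl) +
                      nr * gini_impurity(n1 - left1, nr)) / n;
      if (score < best_score - 1e-12) {
        best_score = score;
        best_f = f;
        best_thresh = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo,hi) in place, preserving relative order for determinism
  std::stable_partition(idx.begin() + lo, idx.begin() + hi,
                        [&](int r) { return X(r, best_f) <= best_thresh; });
  int mid = lo;
  while (mid < hi && X(idx[mid], best_f) <= best_thresh) ++mid;
  if (mid == lo || mid == hi) return;

  nodes[node_id].feature = best_f;
  nodes[node_id].thresh = best_thresh;
  int lid = (int)nodes.size(); nodes.push_back(TreeNode());
  int rid = (int)nodes.size(); nodes.push_back(TreeNode());
  nodes[node_id].left = lid;
  nodes[node_id].right = rid;
  build_node(X, y, idx, lo, mid, depth + 1, mtry, min_node, max_depth, rng,
             nodes, lid);
  build_node(X, y, idx, mid, hi, depth + 1, mtry, min_node, max_depth, rng,
             nodes, rid);
}

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  List forest(n_trees);
  for (int tr = 0; tr < n_trees; ++tr) {
    XorShift rng(((uint64_t)(uint32_t)seed << 20) + (uint64_t)tr + 1ULL);
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) idx[t] = rng.unif_int(n);  // bootstrap
    std::vector<TreeNode> nodes;
    nodes.push_back(TreeNode());
    build_node(X, y, idx, 0, n, 0, mtry, min_node, max_depth, rng, nodes, 0);
    const int m = (int)nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector thresh(m), prob(m);
    for (int t = 0; t < m; ++t) {
      feature[t] = nodes[t].feature;
      thresh[t] = nodes[t].feature >= 0 ? nodes[t].thresh : 0.0;
      left[t] = nodes[t].feature >= 0 ? nodes[t].left : -1;
      right[t] = nodes[t].feature >= 0 ? nodes[t].right : -1;
      prob[t] = nodes[t].prob;
    }
    forest[tr] = List::create(_["feature"] = feature, _["thresh"] = thresh,
                              _["left"] = left, _["right"] = right,
                              _["prob"] = prob);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int tr = 0; tr < T; ++tr) {
    List tree = forest[tr];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector thresh = tree["thresh"], prob = tree["prob"];
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(r, feature[node]) <= thresh[node] ? left[node] : right[node];
      out[r] += prob[node];
    }
  }
  return out / (double)T;
}
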