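// Core honest causal tree / forest engine.
//
// Trees are grown on a "split half" of each subsample (choosing variables and
// thresholds) and their leaf effects are estimated on the disjoint "estimate
// half" (honesty). The split criterion is the direct difference-in-means
// heterogeneity criterion: maximize sum_children n_child * tau_child^2, with
// tau_child the within-child treated-minus-control mean outcome on the split
// half, subject to a minimum per-arm leaf size on BOTH halves. Candidate
// thresholds are midpoints between consecutive distinct observed values on the
// split half; ties in the criterion keep the lowest variable index, then the
// smallest threshold (candidates are scanned in that order and replaced only
// on strict improvement), so fits are deterministic given the seed.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: small, fast, deterministic across platforms.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n); modulo bias is negligible for n << 2^64
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// first k elements of a partial Fisher-Yates shuffle of v
void partial_shuffle(std::vector<int>& v, int k, SplitMix64& rng) {
  const int n = static_cast<int>(v.size());
  for (int i = 0; i < k && i < n - 1; ++i) {
    int j = i + rng.unif_int(n - i);
    std::swap(v[i], v[j]);
  }
}

struct SortItem {
  double x;
  double y;
  int d;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& Y;
  const IntegerVector& D;
  const double* Xp;  // column-major data pointer
  int nrowX;
  int min_leaf, mtry, max_depth;
  SplitMix64 rng;

  // reusable per-node workspaces (filled before recursing)
  std::vector<SortItem> ws_split, ws_est;
  std::vector<int> ws_vars;

  // node arrays (index 0 = root); var = -1 marks a leaf
  std::vector<int> var, left, right, n0e, n1e;
  std::vector<double> thr, tau, mu0, mu1;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& Y_,
              const IntegerVector& D_, int min_leaf_, int mtry_,
              int max_depth_, uint64_t seed)
      : X(X_), Y(Y_), D(D_), Xp(&X_(0, 0)), nrowX(X_.nrow()),
        min_leaf(min_leaf_), mtry(mtry_), max_depth(max_depth_), rng(seed) {}

  int new_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    n0e.push_back(0); n1e.push_back(0);
    thr.push_back(NA_REAL); tau.push_back(NA_REAL);
    mu0.push_back(NA_REAL); mu1.push_back(NA_REAL);
    return static_cast<int>(var.size()) - 1;
  }

  void make_leaf(int node, const std::vector<int>& est) {
    double s0 = 0.0, s1 = 0.0;
    int c0 = 0, c1 = 0;
    for (int i : est) {
      if (D[i] == 1) { s1 += Y[i]; ++c1; } else { s0 += Y[i]; ++c0; }
    }
    n0e[node] = c0; n1e[node] = c1;
    mu0[node] = c0 > 0 ? s0 / c0 : NA_REAL;
    mu1[node] = c1 > 0 ? s1 / c1 : NA_REAL;
    tau[node] = (c0 > 0 && c1 > 0) ? mu1[node] - mu0[node] : NA_REAL;
  }

  int build(std::vector<int>& split_rows, std::vector<int>& est_rows, int depth) {
    const int node = new_node();
    const int p = X.ncol();

    if (max_depth >= 0 && depth >= max_depth) { make_leaf(node, est_rows); return node; }

    // cheap guards: a valid split needs >= 2*min_leaf per arm on both halves
    int s1 = 0, s0 = 0, e1 = 0, e0 = 0;
    for (int i : split_rows) (D[i] == 1 ? s1 : s0)++;
    for (int i : est_rows) (D[i] == 1 ? e1 : e0)++;
    if (s1 < 2 * min_leaf || s0 < 2 * min_leaf ||
        e1 < 2 * min_leaf || e0 < 2 * min_leaf) {
      make_leaf(node, est_rows); return node;
    }

    // candidate variables: mtry sampled without replacement, scanned ascending
    ws_vars.resize(p);
    for (int j = 0; j < p; ++j) ws_vars[j] = j;
    int m = std::min(mtry, p);
    partial_shuffle(ws_vars, m, rng);
    ws_vars.resize(m);
    std::sort(ws_vars.begin(), ws_vars.end());
    const std::vector<int> vars(ws_vars);

    const int nS = static_cast<int>(split_rows.size());
    const int nE = static_cast<int>(est_rows.size());

    double best_crit = -1.0, best_thr = NA_REAL;
    int best_var = -1;

    ws_split.resize(nS);
    ws_est.resize(nE);
    SortItem* S = ws_split.data();
    SortItem* E = ws_est.data();

    // split-half totals (arm counts / outcome sums) are split-invariant
    int N1 = 0, N0 = 0;
    double S1t = 0.0, S0t = 0.0;
    for (int k = 0; k < nS; ++k) {
      const int i = split_rows[k];
      if (D[i] == 1) { ++N1; S1t += Y[i]; } else { ++N0; S0t += Y[i]; }
    }

    for (int j : vars) {
      const double* xj = Xp + static_cast<size_t>(j) * nrowX;
      for (int k = 0; k < nS; ++k) {
        const int i = split_rows[k];
        S[k].x = xj[i];
        S[k].y = Y[i];
        S[k].d = D[i];
      }
      std::sort(S, S + nS,
                [](const SortItem& a, const SortItem& b) { return a.x < b.x; });
      if (S[0].x == S[nS - 1].x) continue;  // constant on split half

      for (int k = 0; k < nE; ++k) {
        const int i = est_rows[k];
        E[k].x = xj[i];
        E[k].d = D[i];
      }
      std::sort(E, E + nE,
                [](const SortItem& a, const SortItem& b) { return a.x < b.x; });

      // running left-side sums; thresholds scanned in ascending order
      int n1l = 0, n0l = 0, ep = 0, e1l = 0, e0l = 0;
      double s1l = 0.0, s0l = 0.0;
      for (int k = 1; k < nS; ++k) {
        if (S[k - 1].d == 1) { ++n1l; s1l += S[k - 1].y; }
        else { ++n0l; s0l += S[k - 1].y; }
        const double lo = S[k - 1].x, hi = S[k].x;
        if (lo == hi) continue;
        const double t = (lo + hi) / 2.0;
        if (!(t > lo && t <= hi)) continue;  // degenerate midpoint guard

        const int n1r = N1 - n1l, n0r = N0 - n0l;
        if (n1l < min_leaf || n0l < min_leaf || n1r < min_leaf || n0r < min_leaf)
          continue;

        while (ep < nE && E[ep].x < t) {
          (E[ep].d == 1 ? e1l : e0l)++;
          ++ep;
        }
        if (e1l < min_leaf || e0l < min_leaf ||
            e1 - e1l < min_leaf || e0 - e0l < min_leaf)
          continue;

        const double tauL = s1l / n1l - s0l / n0l;
        const double tauR = (S1t - s1l) / n1r - (S0t - s0l) / n0r;
        const double crit = (n1l + n0l) * tauL * tauL + (n1r + n0r) * tauR * tauR;
        if (crit > best_crit) { best_crit = crit; best_var = j; best_thr = t; }
      }
    }

    if (best_var < 0) { make_leaf(node, est_rows); return node; }

    std::vector<int> sl, sr, el, er;
    for (int i : split_rows) (X(i, best_var) < best_thr ? sl : sr).push_back(i);
    for (int i : est_rows) (X(i, best_var) < best_thr ? el : er).push_back(i);

    var[node] = best_var;
    thr[node] = best_thr;
    const int l = build(sl, el, depth + 1);
    const int r = build(sr, er, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }

  List as_list() const {
    return List::create(
        _["var"] = IntegerVector(var.begin(), var.end()),
        _["threshold"] = NumericVector(thr.begin(), thr.end()),
        _["left"] = IntegerVector(left.begin(), left.end()),
        _["right"] = IntegerVector(right.begin(), right.end()),
        _["tau"] = NumericVector(tau.begin(), tau.end()),
        _["mu0"] = NumericVector(mu0.begin(), mu0.end()),
        _["mu1"] = NumericVector(mu1.begin(), mu1.end()),
        _["n0_est"] = IntegerVector(n0e.begin(), n0e.end()),
        _["n1_est"] = IntegerVector(n1e.begin(), n1e.end()));
  }
};

}  // namespace

// [[Rcpp::export(name = ".cf_fit_tree")]]
List cf_fit_tree(NumericMatrix X, NumericVector Y, IntegerVector D,
                 IntegerVector split_ids, IntegerVector est_ids,
                 int min_leaf, int mtry, int max_depth, double seed) {
  std::vector<int> sr(split_ids.begin(), split_ids.end());
  std::vector<int> er(est_ids.begin(), est_ids.end());
  for (auto& i : sr) --i;  // to 0-based
  for (auto& i : er) --i;
  TreeBuilder tb(X, Y, D, min_leaf, mtry, max_depth,
                 static_cast<uint64_t>(seed));
  tb.build(sr, er, 0);
  return tb.as_list();
}

// [[Rcpp::export(name = ".cf_fit_forest")]]
List cf_fit_forest(NumericMatrix X, NumericVector Y, IntegerVector D,
                   int num_trees, double subsample_fraction,
                   double honesty_fraction, int min_leaf, int mtry,
                   int max_depth, int ci_group_size, double seed) {
  const int n = X.nrow();
  const int s = std::max(1, ci_group_size);
  const int B = ((num_trees + s - 1) / s) * s;  // round up to full groups
  const int G = B / s;
  const int nh = n / 2;  // shared half-sample per group
  int ns = static_cast<int>(std::floor(subsample_fraction * n));
  ns = std::min(std::max(ns, 4), nh);

  List trees(B), inbag(B);
  IntegerVector group(B);
  SplitMix64 master(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  int b = 0;
  for (int g = 0; g < G; ++g) {
    SplitMix64 grng(master.next());
    std::vector<int> half(all);
    partial_shuffle(half, nh, grng);
    half.resize(nh);
    for (int t = 0; t < s; ++t, ++b) {
      std::vector<int> sub(half);
      partial_shuffle(sub, ns, grng);
      sub.resize(ns);
      // honesty split: first part determines splits, remainder estimates
      int nsplit = static_cast<int>(std::floor(honesty_fraction * ns));
      nsplit = std::min(std::max(nsplit, 1), ns - 1);
      std::vector<int> split_rows(sub.begin(), sub.begin() + nsplit);
      std::vector<int> est_rows(sub.begin() + nsplit, sub.end());
      TreeBuilder tb(X, Y, D, min_leaf, mtry, max_depth, grng.next());
      tb.build(split_rows, est_rows, 0);
      trees[b] = tb.as_list();
      IntegerVector ib(sub.size());
      for (size_t k = 0; k < sub.size(); ++k) ib[k] = sub[k] + 1;
      std::sort(ib.begin(), ib.end());
      inbag[b] = ib;
      group[b] = g + 1;
    }
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["group"] = group, _["num_trees"] = B,
                      _["ci_group_size"] = s);
}

// Per-tree leaf statistics for each query row. Returns n x B matrices of the
// honest leaf effect (tau) and the honest per-arm leaf means (mu0, mu1).
// [[Rcpp::export(name = ".cf_predict_raw")]]
List cf_predict_raw(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericMatrix tau(n, B), mu0(n, B), mu1(n, B);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"], ltau = tr["tau"], lmu0 = tr["mu0"],
                  lmu1 = tr["mu1"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (var[node] >= 0)
        node = X(i, var[node]) < thr[node] ? left[node] : right[node];
      tau(i, b) = ltau[node];
      mu0(i, b) = lmu0[node];
      mu1(i, b) = lmu1[node];
    }
  }
  return List::create(_["tau"] = tau, _["mu0"] = mu0, _["mu1"] = mu1);
}

// Depth-weighted split counts: for each variable and depth d = 0,1,...,
// max_depth_considered - 1, the number of internal nodes at that depth
// splitting on the variable, plus the per-depth totals. Used by
// variable_importance().
// [[Rcpp::export(name = ".cf_split_counts")]]
List cf_split_counts(List trees, int p, int max_depth_considered) {
  NumericMatrix counts(p, max_depth_considered);
  NumericVector totals(max_depth_considered);
  const int B = trees.size();
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    const int nn = var.size();
    std::vector<int> depth(nn, 0);
    for (int k = 0; k < nn; ++k) {
      if (var[k] >= 0) {
        depth[left[k]] = depth[k] + 1;
        depth[right[k]] = depth[k] + 1;
        if (depth[k] < max_depth_considered) {
          counts(var[k], depth[k]) += 1.0;
          totals[depth[k]] += 1.0;
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["totals"] = totals);
}
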