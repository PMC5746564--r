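#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Unpruned CART regression trees grown on externally supplied bootstrap
// resamples, with random feature subsampling (mtry) at each node.  Trees are
// flattened into parallel node arrays: var < 0 marks a terminal node.  All
// randomness flows through R's RNG so set.seed() governs the whole fit.

namespace {

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, nodesize;
  std::vector<int> var, left, right;
  std::vector<double> thr, value;

  Grower(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
         int nodesize_)
      : X(X_), y(y_), mtry(mtry_), nodesize(nodesize_) {}

  int grow(std::vector<int>& idx) {
    const int node = static_cast<int>(var.size());
    const int n = static_cast<int>(idx.size());
    double sum = 0.0;
    for (int i : idx) sum += y[i];
    var.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(sum / n);

    if (n <= nodesize) return node;
    bool pure = true;
    for (int i : idx)
      if (y[i] != y[idx[0]]) { pure = false; break; }
    if (pure) return node;

    const int p = X.ncol();
    const int m = std::min(mtry, p);
    std::vector<int> cols(p);
    for (int j = 0; j < p; ++j) cols[j] = j;

    double bestScore = R_PosInf, bestThr = 0.0;
    int bestVar = -1;
    std::vector<std::pair<double, double> > v;
    v.reserve(n);
    for (int t = 0; t < m; ++t) {
      // partial Fisher-Yates draw of the t-th candidate column
      int k = t + static_cast<int>(unif_rand() * (p - t));
      if (k >= p) k = p - 1;
      std::swap(cols[t], cols[k]);
      const int j = cols[t];
      v.clear();
      for (int i : idx) v.push_back(std::make_pair(X(i, j), y[i]));
      std::sort(v.begin(), v.end());
      if (v.front().first == v.back().first) continue;  // constant in node
      double S = 0.0;
      for (int i = 0; i < n; ++i) S += v[i].second;
      double SL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        SL += v[i].second;
        if (v[i + 1].first == v[i].first) continue;
        const double nL = i + 1.0, nR = n - i - 1.0;
        // minimising child SSE == minimising -(SL^2/nL + SR^2/nR)
        const double SR = S - SL;
        const double score = -(SL * SL / nL + SR * SR / nR);
        if (score < bestScore) {
          bestScore = score;
          bestVar = j;
          bestThr = 0.5 * (v[i].first + v[i + 1].first);
        }
      }
    }
    if (bestVar < 0) return node;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, bestVar) <= bestThr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    var[node] = bestVar;
    thr[node] = bestThr;
    const int L = grow(li);
    left[node] = L;
    const int R = grow(ri);
    right[node] = R;
    return node;
  }
};

inline double tree_pred_row(const IntegerVector& var, const NumericVector& thr,
                            const IntegerVector& left,
                            const IntegerVector& right,
                            const NumericVector& value,
                            const NumericMatrix& X, int i) {
  int nd = 0;
  while (var[nd] >= 0) nd = (X(i, var[nd]) <= thr[nd]) ? left[nd] : right[nd];
  return value[nd];
}

}  // namespace

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, IntegerMatrix inbag,
                     int mtry, int nodesize) {
  RNGScope scope;
  const int k = inbag.ncol(), n = X.nrow();
  List trees(k);
  std::vector<int> idx;
  for (int b = 0; b < k; ++b) {
    idx.clear();
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < inbag(i, b); ++c) idx.push_back(i);
    Grower g(X, y, mtry, nodesize);
    g.grow(idx);
    // 0-based node/variable indices; var == -1 marks a leaf
    trees[b] = List::create(
        _["var"] = IntegerVector(g.var.begin(), g.var.end()),
        _["thr"] = NumericVector(g.thr.begin(), g.thr.end()),
        _["left"] = IntegerVector(g.left.begin(), g.left.end()),
        _["right"] = IntegerVector(g.right.begin(), g.right.end()),
        _["value"] = NumericVector(g.value.begin(), g.value.end()));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_pred_row(var, thr, left, right, value, X, i);
  return out;
}

// [[Rcpp::export]]
NumericMatrix predict_forest_all_cpp(List trees, NumericMatrix X) {
  const int k = trees.size(), n = X.nrow();
  NumericMatrix out(n, k);
  for (int b = 0; b < k; ++b) {
    List tree = trees[b];
    IntegerVector var = tree["var"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["thr"], value = tree["value"];
    for (int i = 0; i < n; ++i)
      out(i, b) = tree_pred_row(var, thr, left, right, value, X, i);
  }
  return out;
}

// Euclidean distance (in pixel units) from every cell to the nearest TRUE
// cell of `feat`.  Brute force over the feature cell list; grids here are
// small (<= a few hundred cells a side).
// [[Rcpp::export]]
NumericMatrix feature_distance_cpp(LogicalMatrix feat) {
  const int nr = feat.nrow(), nc = feat.ncol();
  std::vector<int> fr, fc;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (feat(i, j)) { fr.push_back(i); fc.push_back(j); }
  NumericMatrix out(nr, nc);
  const int nf = static_cast<int>(fr.size());
  if (nf == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (feat(i, j)) { out(i, j) = 0.0; continue; }
      double best = R_PosInf;
      for (int f = 0; f < nf; ++f) {
        const double dr = i - fr[f], dc = j - fc[f];
        const double d2 = dr * dr + dc * dc;
        if (d2 < best) best = d2;
      }
      out(i, j) = std::sqrt(best);
    }
  }
  return out;
}

// OOB permutation importance: for every tree that used covariate j, permute
// j's values within the tree's OOB set and record the relative MSE
// increase.  Trees with |OOB| < 2 are skipped (counted), trees with zero
// baseline OOB error contribute no ratio.  Permutations use R's RNG.
// [[Rcpp::export]]
List oob_importance_cpp(List trees, NumericMatrix X, NumericVector y,
                        IntegerMatrix inbag, LogicalMatrix var_used,
                        bool detail) {
  RNGScope scope;
  const int k = trees.size(), n = X.nrow(), p = X.ncol();
  NumericVector sum_ratio(p);
  IntegerVector n_ratio(p), n_used(p);
  int n_small_oob = 0;
  std::vector<int> rec_tree, rec_cov;
  std::vector<double> rec_e, rec_ep;
  std::vector<IntegerVector> rec_perm;

  std::vector<int> oob;
  std::vector<int> perm;
  std::vector<double> colbuf;
  for (int b = 0; b < k; ++b) {
    bool any_used = false;
    for (int j = 0; j < p; ++j) any_used = any_used || var_used(b, j);
    if (!any_used) continue;
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) oob.push_back(i);
    const int m = static_cast<int>(oob.size());
    if (m < 2) { ++n_small_oob; continue; }

    List tree = trees[b];
    IntegerVector var = tree["var"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["thr"], value = tree["value"];

    double e_b = 0.0;
    for (int t = 0; t < m; ++t) {
      const int i = oob[t];
      int nd = 0;
      while (var[nd] >= 0)
        nd = (X(i, var[nd]) <= thr[nd]) ? left[nd] : right[nd];
      const double d = y[i] - value[nd];
      e_b += d * d;
    }
    e_b /= m;

    for (int j = 0; j < p; ++j) {
      if (!var_used(b, j)) continue;
      ++n_used[j];
      if (e_b == 0.0) continue;
      // Fisher-Yates permutation of the OOB positions
      perm.resize(m);
      for (int t = 0; t < m; ++t) perm[t] = t;
      for (int t = m - 1; t > 0; --t) {
        int u = static_cast<int>(unif_rand() * (t + 1));
        if (u > t) u = t;
        std::swap(perm[t], perm[u]);
      }
      colbuf.resize(m);
      for (int t = 0; t < m; ++t) colbuf[t] = X(oob[perm[t]], j);
      double e_bp = 0.0;
      for (int t = 0; t < m; ++t) {
        const int i = oob[t];
        int nd = 0;
        while (var[nd] >= 0) {
          const int v = var[nd];
          const double xv = (v == j) ? colbuf[t] : X(i, v);
          nd = (xv <= thr[nd]) ? left[nd] : right[nd];
        }
        const double d = y[i] - value[nd];
        e_bp += d * d;
      }
      e_bp /= m;
      sum_ratio[j] += (e_bp - e_b) / e_b;
      ++n_ratio[j];
      if (detail) {
        rec_tree.push_back(b + 1);
        rec_cov.push_back(j + 1);
        rec_e.push_back(e_b);
        rec_ep.push_back(e_bp);
        IntegerVector pv(m);
        for (int t = 0; t < m; ++t) pv[t] = perm[t] + 1;
        rec_perm.push_back(pv);
      }
    }
  }
  List det = R_NilValue;
  if (detail) {
    List perms(rec_perm.size());
    for (size_t r = 0; r < rec_perm.size(); ++r) perms[r] = rec_perm[r];
    det = List::create(
        _["tree"] = IntegerVector(rec_tree.begin(), rec_tree.end()),
        _["covariate"] = IntegerVector(rec_cov.begin(), rec_cov.end()),
        _["e_oob"] = NumericVector(rec_e.begin(), rec_e.end()),
        _["e_perm"] = NumericVector(rec_ep.begin(), rec_ep.end()),
        _["perm"] = perms);
  }
  return List::create(_["sum_ratio"] = sum_ratio, _["n_ratio"] = n_ratio,
                      _["n_used"] = n_used, _["n_small_oob"] = n_small_oob,
                      _["detail"] = det);
}
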