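// Core of the subject-bootstrapped random forest: Gini split search, tree
// growth to purity, and tree traversal. Kept deliberately small; all
// bootstrap draws and per-tree median imputation live on the R side so that
// every random draw comes from R's RNG and the fitted object is fully
// inspectable from R.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double gini_pair(double a, double b) {
  double n = a + b;
  if (n <= 0.0) return 0.0;
  double pa = a / n, pb = b / n;
  return 1.0 - pa * pa - pb * pb;
}

// Best (feature, threshold) over the supplied rows and candidate features.
// feats must be sorted ascending; thresholds are midpoints between
// consecutive distinct observed values, scanned in ascending order.
// Strict ">" keeps the earliest feature / lowest threshold on ties.
struct SplitResult {
  int feature;       // 0-based column, -1 if none
  double threshold;
  double decrease;
};

static SplitResult best_split_impl(const NumericMatrix& X,
                                   const IntegerVector& y,
                                   const std::vector<int>& rows,
                                   const std::vector<int>& feats) {
  SplitResult best = { -1, NA_REAL, 0.0 };
  const int n = (int) rows.size();
  if (n < 2) return best;

  double tot1 = 0.0;
  for (int i = 0; i < n; ++i) tot1 += y[rows[i]];
  double tot0 = n - tot1;
  double parent = gini_pair(tot0, tot1);
  if (parent <= 0.0) return best;

  std::vector<double> xv(n);
  std::vector<int> ord(n), yv(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) xv[i] = X(rows[i], f);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return xv[a] < xv[b]; });
    double l0 = 0.0, l1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      int r = ord[i];
      if (y[rows[r]] == 1) l1 += 1.0; else l0 += 1.0;
      double xl = xv[r], xr = xv[ord[i + 1]];
      if (!(xl < xr)) continue;
      double nl = l0 + l1, nr = n - nl;
      double dec = parent
        - (nl / n) * gini_pair(l0, l1)
        - (nr / n) * gini_pair(tot0 - l0, tot1 - l1);
      if (dec > best.decrease) {
        best.decrease = dec;
        best.feature = f;
        best.threshold = xl + (xr - xl) / 2.0;
      }
    }
  }
  if (!(best.decrease > 0.0)) best.feature = -1;
  return best;
}

// [[Rcpp::export(name = ".cpp_best_split")]]
List cpp_best_split(NumericMatrix X, IntegerVector y,
                    IntegerVector rows, IntegerVector feats) {
  std::vector<int> rv(rows.begin(), rows.end());
  std::vector<int> fv(feats.begin(), feats.end());
  SplitResult s = best_split_impl(X, y, rv, fv);
  return List::create(_["feature"] = s.feature,
                      _["threshold"] = s.threshold,
                      _["decrease"] = s.decrease);
}

// Grow one tree to purity (min leaf 1) with per-node feature subsampling.
// X must already be imputed (no NA in usable columns); rows carry bootstrap
// multiplicity. Returns parallel arrays describing the tree; children of
// node k are left[k]/right[k] (0-based, -1 for leaves).
// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                   IntegerVector usable_feats, int mtry, int seed) {
  std::mt19937 rng((uint32_t) seed);
  std::vector<int> pool(usable_feats.begin(), usable_feats.end());
  const int npool = (int) pool.size();
  if (mtry > npool) mtry = npool;

  std::vector<int> feature, left, right;
  std::vector<double> threshold, n0, n1;

  struct Work { std::vector<int> rows; int slot; };
  std::vector<Work> stack;
  std::vector<int> all(rows.begin(), rows.end());
  stack.push_back({ all, -1 });
  // slot -1 means root; otherwise index into left/right to patch afterwards
  std::vector<int> patch_side; // unused; we patch via slot encoding below

  // We encode pending child links as (parent_node * 2 + side) in `slot`.
  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();

    double c1 = 0.0;
    for (size_t i = 0; i < w.rows.size(); ++i) c1 += y[w.rows[i]];
    double c0 = (double) w.rows.size() - c1;

    int node = (int) feature.size();
    if (w.slot >= 0) {
      int parent = w.slot / 2;
      if (w.slot % 2 == 0) left[parent] = node; else right[parent] = node;
    }

    SplitResult s = { -1, NA_REAL, 0.0 };
    if (c0 > 0.0 && c1 > 0.0 && w.rows.size() >= 2 && npool > 0) {
      // sample mtry features without replacement, then sort ascending so
      // tie-breaking follows column order
      std::vector<int> cand(pool);
      for (int i = 0; i < mtry; ++i) {
        std::uniform_int_distribution<int> pick(i, npool - 1);
        std::swap(cand[i], cand[pick(rng)]);
      }
      cand.resize(mtry);
      std::sort(cand.begin(), cand.end());
      s = best_split_impl(X, y, w.rows, cand);
    }

    if (s.feature < 0) { // leaf
      feature.push_back(-1);
      threshold.push_back(NA_REAL);
      left.push_back(-1);
      right.push_back(-1);
      n0.push_back(c0);
      n1.push_back(c1);
      continue;
    }

    feature.push_back(s.feature);
    threshold.push_back(s.threshold);
    left.push_back(-2);   // patched when child is emitted
    right.push_back(-2);
    n0.push_back(c0);
    n1.push_back(c1);

    std::vector<int> lr, rr;
    for (size_t i = 0; i < w.rows.size(); ++i) {
      if (X(w.rows[i], s.feature) <= s.threshold) lr.push_back(w.rows[i]);
      else rr.push_back(w.rows[i]);
    }
    // push right first so left is emitted first (stable node numbering)
    stack.push_back({ std::move(rr), node * 2 + 1 });
    stack.push_back({ std::move(lr), node * 2 + 0 });
  }

  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["left"] = wrap(left),
                      _["right"] = wrap(right),
                      _["n0"] = wrap(n0),
                      _["n1"] = wrap(n1));
}

// Predict class (0/1) for each row of X with one tree; NA entries are
// replaced by the tree's stored in-bag medians on the fly.
// [[Rcpp::export(name = ".cpp_predict_tree")]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X,
                               NumericVector medians) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector n0 = tree["n0"], n1 = tree["n1"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      double v = X(i, feature[node]);
      if (NumericVector::is_na(v)) v = medians[feature[node]];
      node = (v <= threshold[node]) ? left[node] : right[node];
    }
    // leaf vote; tie -> class 0 (control), conservative
    out[i] = (n1[node] > n0[node]) ? 1 : 0;
  }
  return out;
}
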