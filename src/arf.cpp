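// Adversarial random forest core: MIA-split classification trees, leaf
// harvesting, truncated-Gaussian / multinomial leaf distributions, and the
// conditional mixture used for imputation.
//
// Data convention: tables are numeric matrices; categorical features carry
// integer level codes 1..k (NA_REAL for missing). ftype[j] == 0 marks a
// continuous feature, ftype[j] == k >= 1 a categorical one with k levels.
// Inside trees the NA "level" of a categorical feature is coded 0.
//
// All randomness goes through R's RNG (unif_rand), so set.seed() on the R
// side fully determines every result.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double SPLIT_EPS = 1e-12;

// ---------------------------------------------------------------------------
// splitting

struct SplitResult {
  bool valid = false;
  double impurity = R_PosInf;  // weighted child Gini
  int feature = -1;            // 0-based
  double threshold = NA_REAL;
  bool na_left = true;
  std::vector<int> left_levels;  // categorical: levels routed left (0 = NA)
};

static inline double gini_pair(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 1.0 - p * p - (1.0 - p) * (1.0 - p);
}

static inline double weighted_gini(double nl, double l1, double nr, double r1) {
  double n = nl + nr;
  return (nl * gini_pair(l1, nl) + nr * gini_pair(r1, nr)) / n;
}

// Best MIA split of one numeric feature. Candidate thresholds are the
// distinct observed values s (x <= s vs x > s); for each, Split A routes NA
// left and Split B routes NA right. Candidates are scanned in the canonical
// order (s ascending, A before B) and only strict improvements are accepted,
// which implements the deterministic tie-break.
static void best_numeric_split(const std::vector<double>& xs,
                               const std::vector<int>& ys,
                               int min_node, SplitResult& best, int feature) {
  int n = (int)xs.size();
  std::vector<std::pair<double, int> > obs;
  obs.reserve(n);
  int nmis = 0, mis1 = 0;
  for (int i = 0; i < n; ++i) {
    if (ISNAN(xs[i])) { ++nmis; mis1 += ys[i]; }
    else obs.push_back(std::make_pair(xs[i], ys[i]));
  }
  int nobs = (int)obs.size();
  if (nobs == 0) return;  // all missing: no numeric split possible
  std::sort(obs.begin(), obs.end());
  std::vector<int> pref(nobs + 1, 0);
  for (int i = 0; i < nobs; ++i) pref[i + 1] = pref[i] + obs[i].second;
  int tot1 = pref[nobs] + mis1;

  for (int i = 0; i < nobs; ++i) {
    if (i < nobs - 1 && obs[i].first == obs[i + 1].first) continue;
    double s = obs[i].first;
    int nlB = i + 1, l1B = pref[i + 1];
    // Split A: NA goes left
    {
      int nl = nlB + nmis, l1 = l1B + mis1;
      int nr = n - nl, r1 = tot1 - l1;
      if (nl >= min_node && nr >= min_node) {
        double imp = weighted_gini(nl, l1, nr, r1);
        if (imp < best.impurity - SPLIT_EPS) {
          best.valid = true; best.impurity = imp; best.feature = feature;
          best.threshold = s; best.na_left = true; best.left_levels.clear();
        }
      }
    }
    // Split B: NA goes right (identical to A when no NAs at the node)
    if (nmis > 0) {
      int nl = nlB, l1 = l1B;
      int nr = n - nl, r1 = tot1 - l1;
      if (nl >= min_node && nr >= min_node) {
        double imp = weighted_gini(nl, l1, nr, r1);
        if (imp < best.impurity - SPLIT_EPS) {
          best.valid = true; best.impurity = imp; best.feature = feature;
          best.threshold = s; best.na_left = false; best.left_levels.clear();
        }
      }
    }
  }
}

// Best split of one categorical feature; NA is treated as an extra level
// (code 0). Levels present at the node are ordered by their class-1 fraction
// (ties by level code) and the optimal binary partition is found by a prefix
// scan, the classic exact search for two-class Gini.
static void best_categorical_split(const std::vector<double>& xs,
                                   const std::vector<int>& ys,
                                   int nlev, int min_node,
                                   SplitResult& best, int feature) {
  int n = (int)xs.size();
  std::vector<int> cnt(nlev + 1, 0), one(nlev + 1, 0);
  for (int i = 0; i < n; ++i) {
    int lv = ISNAN(xs[i]) ? 0 : (int)xs[i];
    cnt[lv]++; one[lv] += ys[i];
  }
  std::vector<int> present;
  for (int g = 0; g <= nlev; ++g) if (cnt[g] > 0) present.push_back(g);
  int G = (int)present.size();
  if (G < 2) return;
  std::sort(present.begin(), present.end(), [&](int a, int b) {
    double pa = (double)one[a] / cnt[a], pb = (double)one[b] / cnt[b];
    if (pa != pb) return pa < pb;
    return a < b;
  });
  int tot1 = 0; for (int g : present) tot1 += one[g];
  int nl = 0, l1 = 0;
  for (int q = 0; q < G - 1; ++q) {
    nl += cnt[present[q]]; l1 += one[present[q]];
    int nr = n - nl, r1 = tot1 - l1;
    if (nl < min_node || nr < min_node) continue;
    double imp = weighted_gini(nl, l1, nr, r1);
    if (imp < best.impurity - SPLIT_EPS) {
      best.valid = true; best.impurity = imp; best.feature = feature;
      best.threshold = NA_REAL;
      best.left_levels.assign(present.begin(), present.begin() + q + 1);
      std::sort(best.left_levels.begin(), best.left_levels.end());
      best.na_left = std::binary_search(best.left_levels.begin(),
                                        best.left_levels.end(), 0);
    }
  }
}

// ---------------------------------------------------------------------------
// tree growing

struct Tree {
  std::vector<int> feature, left, right, na_left, leaf_id, n1, n0;
  std::vector<double> thr;
  std::vector<std::vector<int> > leftlev;
  int n_leaves = 0;
  int new_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    na_left.push_back(1); leaf_id.push_back(-1); n1.push_back(0);
    n0.push_back(0); thr.push_back(NA_REAL);
    leftlev.push_back(std::vector<int>());
    return (int)feature.size() - 1;
  }
};

static void grow_node(Tree& tree, int node, std::vector<int>& rows,
                      const NumericMatrix& X, const IntegerVector& y,
                      const IntegerVector& ftype, int min_node, int mtry) {
  int n = (int)rows.size(), p = X.ncol();
  int n1 = 0; for (int r : rows) n1 += y[r];
  tree.n1[node] = n1; tree.n0[node] = n - n1;

  bool pure = (n1 == 0 || n1 == n);
  SplitResult best;
  if (!pure && n >= 2 * min_node) {
    // draw an mtry-subset of features, scan in ascending index order
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {  // partial Fisher-Yates
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
    feats.resize(mtry);
    std::sort(feats.begin(), feats.end());

    double parent = gini_pair(n1, n);
    std::vector<double> xs(n); std::vector<int> ys(n);
    for (int f = 0; f < (int)feats.size(); ++f) {
      int j = feats[f];
      for (int i = 0; i < n; ++i) { xs[i] = X(rows[i], j); ys[i] = y[rows[i]]; }
      if (ftype[j] == 0) best_numeric_split(xs, ys, min_node, best, j);
      else best_categorical_split(xs, ys, ftype[j], min_node, best, j);
    }
    if (best.valid && parent - best.impurity <= SPLIT_EPS) best.valid = false;
  }

  if (!best.valid) {
    tree.leaf_id[node] = tree.n_leaves++;
    return;
  }

  std::vector<int> lrows, rrows;
  int j = best.feature;
  for (int r : rows) {
    double v = X(r, j);
    bool goleft;
    if (ftype[j] == 0) {
      goleft = ISNAN(v) ? best.na_left : (v <= best.threshold);
    } else {
      int lv = ISNAN(v) ? 0 : (int)v;
      goleft = std::binary_search(best.left_levels.begin(),
                                  best.left_levels.end(), lv);
    }
    if (goleft) lrows.push_back(r); else rrows.push_back(r);
  }
  rows.clear(); rows.shrink_to_fit();

  tree.feature[node] = j;
  tree.thr[node] = best.threshold;
  tree.na_left[node] = best.na_left ? 1 : 0;
  tree.leftlev[node] = best.left_levels;
  int lid = tree.new_node(), rid = tree.new_node();
  tree.left[node] = lid; tree.right[node] = rid;
  grow_node(tree, lid, lrows, X, y, ftype, min_node, mtry);
  grow_node(tree, rid, rrows, X, y, ftype, min_node, mtry);
}

static int route_row(const IntegerMatrix& nodes, const NumericVector& thr,
                     const List& leftlev, const IntegerVector& ftype,
                     const NumericMatrix& X, int row) {
  int node = 0;
  while (nodes(node, 0) >= 0) {
    int j = nodes(node, 0);
    double v = X(row, j);
    bool goleft;
    if (ftype[j] == 0) {
      goleft = ISNAN(v) ? (nodes(node, 3) == 1) : (v <= thr[node]);
    } else {
      IntegerVector ll = leftlev[node];
      int lv = ISNAN(v) ? 0 : (int)v;
      goleft = false;
      for (int q = 0; q < ll.size(); ++q) if (ll[q] == lv) { goleft = true; break; }
    }
    node = goleft ? nodes(node, 1) : nodes(node, 2);
  }
  return nodes(node, 4);  // leaf id
}

static List tree_to_list(const Tree& t) {
  int K = (int)t.feature.size();
  IntegerMatrix nodes(K, 7);
  NumericVector thr(K);
  List leftlev(K);
  for (int i = 0; i < K; ++i) {
    nodes(i, 0) = t.feature[i]; nodes(i, 1) = t.left[i];
    nodes(i, 2) = t.right[i]; nodes(i, 3) = t.na_left[i];
    nodes(i, 4) = t.leaf_id[i]; nodes(i, 5) = t.n1[i]; nodes(i, 6) = t.n0[i];
    thr[i] = t.thr[i];
    leftlev[i] = wrap(t.leftlev[i]);
  }
  colnames(nodes) = CharacterVector::create("feature", "left", "right",
                                            "na_left", "leaf_id", "n1", "n0");
  return List::create(_["nodes"] = nodes, _["thr"] = thr,
                      _["leftlev"] = leftlev, _["n_leaves"] = t.n_leaves);
}

// Grow a forest of MIA classification trees on the stacked real(1)/synth(0)
// table and report the out-of-bag majority-vote accuracy (vote ties broken
// toward class 0).
// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int num_trees,
                     int min_node_size, int mtry, IntegerVector ftype) {
  int n = X.nrow();
  List trees(num_trees);
  std::vector<int> votes1(n, 0), votes(n, 0);

  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> inbag_cnt(n, 0), rows(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      rows[i] = r; inbag_cnt[r]++;
    }
    Tree tr;
    int root = tr.new_node(); (void)root;
    grow_node(tr, 0, rows, X, y, ftype, min_node_size, mtry);
    List tl = tree_to_list(tr);
    trees[t] = tl;

    IntegerMatrix nodes = tl["nodes"];
    NumericVector thr = tl["thr"];
    List ll = tl["leftlev"];
    // leaf majority labels from in-bag counts; walk to the leaf *node*
    // (route_row returns leaf ids, so predict via node walk here)
    for (int i = 0; i < n; ++i) {
      if (inbag_cnt[i] > 0) continue;
      int node = 0;
      while (nodes(node, 0) >= 0) {
        int j = nodes(node, 0);
        double v = X(i, j);
        bool goleft;
        if (ftype[j] == 0) goleft = ISNAN(v) ? (nodes(node, 3) == 1) : (v <= thr[node]);
        else {
          IntegerVector lev = ll[node];
          int lv = ISNAN(v) ? 0 : (int)v;
          goleft = false;
          for (int q = 0; q < lev.size(); ++q) if (lev[q] == lv) { goleft = true; break; }
        }
        node = goleft ? nodes(node, 1) : nodes(node, 2);
      }
      int pred = nodes(node, 5) > nodes(node, 6) ? 1 : 0;
      votes[i]++; votes1[i] += pred;
    }
  }

  int used = 0, correct = 0;
  for (int i = 0; i < n; ++i) {
    if (votes[i] == 0) continue;
    int pred = (2 * votes1[i] > votes[i]) ? 1 : 0;  // tie -> class 0
    ++used; if (pred == y[i]) ++correct;
  }
  double acc = used > 0 ? (double)correct / used : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_accuracy"] = acc);
}

// Leaf membership of every row in every tree.
// [[Rcpp::export]]
IntegerMatrix cpp_route(List trees, NumericMatrix X, IntegerVector ftype) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerMatrix nodes = tl["nodes"];
    NumericVector thr = tl["thr"];
    List ll = tl["leftlev"];
    for (int i = 0; i < n; ++i) out(i, t) = route_row(nodes, thr, ll, ftype, X, i);
  }
  return out;
}

// Leaf-wise synthetic sampling: per synthetic row draw a tree uniformly and a
// leaf with probability n_tl/n_t (realised by drawing a uniform real row and
// taking its leaf), then bootstrap each feature independently from the real
// cells of that leaf's members. Missing markers are drawable cells.
// [[Rcpp::export]]
NumericMatrix cpp_leafwise_synth(NumericMatrix Xreal, IntegerMatrix membership,
                                 List leaf_members) {
  // leaf_members: list over trees; each a list over leaves of integer vectors
  // of 0-based real-row indices (precomputed in R from `membership`).
  int n = Xreal.nrow(), p = Xreal.ncol(), T = membership.ncol();
  NumericMatrix out(n, p);
  for (int i = 0; i < n; ++i) {
    int t = (int)(unif_rand() * T); if (t >= T) t = T - 1;
    int r = (int)(unif_rand() * n); if (r >= n) r = n - 1;
    int leaf = membership(r, t);
    List tl = leaf_members[t];
    IntegerVector mem = tl[leaf];
    int m = mem.size();
    for (int j = 0; j < p; ++j) {
      int k = (int)(unif_rand() * m); if (k >= m) k = m - 1;
      out(i, j) = Xreal(mem[k], j);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// leaf extraction: hyperrectangle bounds by walking root-to-leaf paths

// [[Rcpp::export]]
List cpp_extract_leaves(List trees, IntegerVector ftype) {
  int T = trees.size(), p = ftype.size();
  int L = 0;
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    L += as<int>(tl["n_leaves"]);
  }
  NumericMatrix lo(L, p), hi(L, p);
  IntegerMatrix na_ok(L, p);        // NA admitted along the path (cont & cat)
  IntegerVector tree_of(L), leaf_of(L);
  List admiss(p);                   // per cat feature: L x k logical
  std::vector<LogicalMatrix> adm;
  for (int j = 0; j < p; ++j) {
    if (ftype[j] > 0) adm.push_back(LogicalMatrix(L, ftype[j]));
    else adm.push_back(LogicalMatrix(0, 0));
  }

  int base = 0;
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerMatrix nodes = tl["nodes"];
    NumericVector thr = tl["thr"];
    List ll = tl["leftlev"];
    int nl = as<int>(tl["n_leaves"]);

    // DFS with explicit stack carrying bounds
    struct Frame { int node; std::vector<double> lo, hi; std::vector<char> naok;
                   std::vector<std::vector<char> > adm; };
    std::vector<Frame> stack;
    Frame root;
    root.node = 0;
    root.lo.assign(p, R_NegInf); root.hi.assign(p, R_PosInf);
    root.naok.assign(p, 1);
    root.adm.resize(p);
    for (int j = 0; j < p; ++j)
      if (ftype[j] > 0) root.adm[j].assign(ftype[j], 1);
    stack.push_back(root);

    while (!stack.empty()) {
      Frame fr = stack.back(); stack.pop_back();
      int node = fr.node;
      if (nodes(node, 0) < 0) {
        int gid = base + nodes(node, 4);
        tree_of[gid] = t; leaf_of[gid] = nodes(node, 4);
        for (int j = 0; j < p; ++j) {
          lo(gid, j) = fr.lo[j]; hi(gid, j) = fr.hi[j];
          na_ok(gid, j) = fr.naok[j];
          if (ftype[j] > 0)
            for (int v = 0; v < ftype[j]; ++v) adm[j](gid, v) = fr.adm[j][v];
        }
        continue;
      }
      int j = nodes(node, 0);
      Frame lf = fr, rf = fr;
      lf.node = nodes(node, 1); rf.node = nodes(node, 2);
      if (ftype[j] == 0) {
        double s = thr[node];
        lf.hi[j] = std::min(fr.hi[j], s);
        rf.lo[j] = std::max(fr.lo[j], s);
        bool naleft = nodes(node, 3) == 1;
        lf.naok[j] = fr.naok[j] && naleft;
        rf.naok[j] = fr.naok[j] && !naleft;
      } else {
        IntegerVector lev = ll[node];
        std::vector<char> inleft(ftype[j] + 1, 0);
        bool na_l = false;
        for (int q = 0; q < lev.size(); ++q) {
          if (lev[q] == 0) na_l = true; else inleft[lev[q]] = 1;
        }
        for (int v = 0; v < ftype[j]; ++v) {
          lf.adm[j][v] = fr.adm[j][v] && inleft[v + 1];
          rf.adm[j][v] = fr.adm[j][v] && !inleft[v + 1];
        }
        lf.naok[j] = fr.naok[j] && na_l;
        rf.naok[j] = fr.naok[j] && !na_l;
      }
      stack.push_back(rf); stack.push_back(lf);
    }
    base += nl;
  }
  for (int j = 0; j < p; ++j) admiss[j] = (ftype[j] > 0) ? (SEXP)adm[j] : R_NilValue;
  return List::create(_["lo"] = lo, _["hi"] = hi, _["na_ok"] = na_ok,
                      _["tree"] = tree_of, _["leaf"] = leaf_of,
                      _["admiss"] = admiss);
}

// ---------------------------------------------------------------------------
// truncated-Gaussian maximum likelihood

// log(Phi(b) - Phi(a)) computed stably via log-tails.
static double log_trunc_mass(double a, double b) {
  if (a == R_NegInf && b == R_PosInf) return 0.0;
  if (b <= a) return R_NegInf;
  if (a + b <= 0.0) {  // work in the lower tail
    double lb = R::pnorm(b, 0.0, 1.0, 1, 1);
    if (a == R_NegInf) return lb;
    double la = R::pnorm(a, 0.0, 1.0, 1, 1);
    double d = la - lb;
    return lb + log1p(-exp(d));
  } else {             // upper tail: Phi(b)-Phi(a) = Phibar(a)-Phibar(b)
    double la = R::pnorm(a, 0.0, 1.0, 0, 1);
    if (b == R_PosInf) return la;
    double lb = R::pnorm(b, 0.0, 1.0, 0, 1);
    double d = lb - la;
    return la + log1p(-exp(d));
  }
}

struct TruncNLL {
  const std::vector<double>& x;
  double lo, hi;
  double operator()(double mu, double logs) const {
    double s = exp(logs);
    if (!R_finite(s) || s <= 0) return R_PosInf;
    double ss = 0.0;
    for (double v : x) { double z = (v - mu) / s; ss += z * z; }
    double lz = log_trunc_mass((lo - mu) / s, (hi - mu) / s);
    if (!R_finite(lz)) return R_PosInf;
    return 0.5 * ss + x.size() * (logs + lz);
  }
};

// Compact 2-d Nelder-Mead on (mu, log sigma).
static void nelder_mead2(const TruncNLL& f, double& mu, double& logs) {
  const int maxit = 400;
  const double tol = 1e-10;
  double px[3] = {mu, mu + 0.5, mu};
  double py[3] = {logs, logs, logs + 0.5};
  double fv[3];
  for (int i = 0; i < 3; ++i) fv[i] = f(px[i], py[i]);
  for (int it = 0; it < maxit; ++it) {
    int lo_i = 0, hi_i = 0, mid = 0;
    for (int i = 1; i < 3; ++i) {
      if (fv[i] < fv[lo_i]) lo_i = i;
      if (fv[i] > fv[hi_i]) hi_i = i;
    }
    for (int i = 0; i < 3; ++i) if (i != lo_i && i != hi_i) mid = i;
    if (hi_i == lo_i) break;
    if (std::fabs(fv[hi_i] - fv[lo_i]) < tol * (std::fabs(fv[lo_i]) + tol)) break;
    double cx = (px[lo_i] + px[mid]) / 2.0, cy = (py[lo_i] + py[mid]) / 2.0;
    double rx = cx + (cx - px[hi_i]), ry = cy + (cy - py[hi_i]);
    double fr = f(rx, ry);
    if (fr < fv[lo_i]) {
      double ex = cx + 2.0 * (cx - px[hi_i]), ey = cy + 2.0 * (cy - py[hi_i]);
      double fe = f(ex, ey);
      if (fe < fr) { px[hi_i] = ex; py[hi_i] = ey; fv[hi_i] = fe; }
      else { px[hi_i] = rx; py[hi_i] = ry; fv[hi_i] = fr; }
    } else if (fr < fv[mid]) {
      px[hi_i] = rx; py[hi_i] = ry; fv[hi_i] = fr;
    } else {
      double kx = cx + 0.5 * (px[hi_i] - cx), ky = cy + 0.5 * (py[hi_i] - cy);
      double fk = f(kx, ky);
      if (fk < fv[hi_i]) { px[hi_i] = kx; py[hi_i] = ky; fv[hi_i] = fk; }
      else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo_i) continue;
          px[i] = px[lo_i] + 0.5 * (px[i] - px[lo_i]);
          py[i] = py[lo_i] + 0.5 * (py[i] - py[lo_i]);
          fv[i] = f(px[i], py[i]);
        }
      }
    }
  }
  int besti = 0;
  for (int i = 1; i < 3; ++i) if (fv[i] < fv[besti]) besti = i;
  mu = px[besti]; logs = py[besti];
}

static void truncnorm_mle(const std::vector<double>& x, double lo, double hi,
                          double& mu, double& sigma) {
  int n = (int)x.size();
  double m = 0.0; for (double v : x) m += v; m /= n;
  double ss = 0.0; for (double v : x) ss += (v - m) * (v - m);
  double s = std::sqrt(ss / n);
  if (n == 1 || s == 0.0) { mu = m; sigma = 0.0; return; }
  if (lo == R_NegInf && hi == R_PosInf) { mu = m; sigma = s; return; }
  TruncNLL f{x, lo, hi};
  double mu0 = m, ls0 = std::log(s);
  nelder_mead2(f, mu0, ls0);
  mu = mu0; sigma = std::exp(ls0);
}

// [[Rcpp::export]]
NumericVector cpp_truncnorm_mle(NumericVector x, double lo, double hi) {
  std::vector<double> v(x.begin(), x.end());
  double mu, sigma;
  truncnorm_mle(v, lo, hi, mu, sigma);
  return NumericVector::create(_["mu"] = mu, _["sigma"] = sigma);
}

// Single-feature MIA split search, exposed for oracle testing. Returns the
// impurity-minimizing split of this column alone (no mtry subsampling).
// [[Rcpp::export]]
List cpp_best_mia_split(NumericVector x, IntegerVector y, int ftype_j,
                        int min_node_size) {
  int n = x.size();
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> ys(y.begin(), y.end());
  int n1 = 0; for (int v : ys) n1 += v;
  SplitResult best;
  if (n1 > 0 && n1 < n && n >= 2 * min_node_size) {
    if (ftype_j == 0) best_numeric_split(xs, ys, min_node_size, best, 0);
    else best_categorical_split(xs, ys, ftype_j, min_node_size, best, 0);
    double parent = gini_pair(n1, n);
    if (best.valid && parent - best.impurity <= SPLIT_EPS) best.valid = false;
  }
  return List::create(_["valid"] = best.valid, _["impurity"] = best.impurity,
                      _["threshold"] = best.threshold,
                      _["na_left"] = best.na_left,
                      _["left_levels"] = wrap(best.left_levels));
}

// ---------------------------------------------------------------------------
// leaf distribution fitting

// [[Rcpp::export]]
List cpp_fit_leaves(List leaves, IntegerMatrix membership, NumericMatrix Xreal,
                    IntegerVector ftype, NumericVector marg_mean,
                    NumericVector marg_sd, List marg_cat,
                    double alpha, NumericVector sigma_floor) {
  NumericMatrix lo = leaves["lo"], hi = leaves["hi"];
  IntegerVector tree_of = leaves["tree"], leaf_of = leaves["leaf"];
  List admiss = leaves["admiss"];
  int L = lo.nrow(), p = lo.ncol();
  int n = Xreal.nrow(), T = membership.ncol();

  // map (tree, leaf-in-tree) -> global leaf index, then member lists
  std::vector<std::vector<int> > base_of(T);
  std::vector<int> tree_base(T, 0);
  {
    std::vector<int> cnt(T, 0);
    for (int l = 0; l < L; ++l) cnt[tree_of[l]]++;
    int b = 0;
    for (int t = 0; t < T; ++t) { tree_base[t] = b; b += cnt[t]; }
  }
  // global index = tree_base[t] + leaf_of (leaves stored tree-major in order)
  std::vector<std::vector<int> > members(L);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      members[tree_base[t] + membership(i, t)].push_back(i);

  NumericVector w(L), n_tl(L);
  NumericMatrix mu(L, p), sigma(L, p), emp_mean(L, p);
  List cat_probs(p);
  std::vector<NumericMatrix> cp;
  for (int j = 0; j < p; ++j)
    cp.push_back(ftype[j] > 0 ? NumericMatrix(L, ftype[j]) : NumericMatrix(0, 0));

  for (int l = 0; l < L; ++l) {
    const std::vector<int>& mem = members[l];
    n_tl[l] = (double)mem.size();
    w[l] = n_tl[l] / ((double)T * n);
    for (int j = 0; j < p; ++j) {
      if (ftype[j] == 0) {
        std::vector<double> vals;
        for (int r : mem) { double v = Xreal(r, j); if (!ISNAN(v)) vals.push_back(v); }
        if (vals.empty()) {
          mu(l, j) = marg_mean[j];
          sigma(l, j) = std::max(marg_sd[j], sigma_floor[j]);
          emp_mean(l, j) = NA_REAL;
        } else if (vals.size() == 1) {
          // a single observation carries no scale: inherit the marginal SD
          mu(l, j) = vals[0];
          sigma(l, j) = std::max(marg_sd[j], sigma_floor[j]);
          emp_mean(l, j) = vals[0];
        } else {
          double m = 0.0; for (double v : vals) m += v;
          m /= vals.size();
          emp_mean(l, j) = m;
          double ss = 0.0; for (double v : vals) ss += (v - m) * (v - m);
          double smom = std::sqrt(ss / vals.size());
          double mh, sh;
          truncnorm_mle(vals, lo(l, j), hi(l, j), mh, sh);
          // trust region: the truncated-Gaussian likelihood is flat (or
          // divergent) for thin leaves; reject runaway optima in favor of
          // the sample moments
          double cap = 2.0 * marg_sd[j];
          double span = 4.0 * std::max(marg_sd[j], smom);
          if (!R_finite(mh) || !R_finite(sh) || sh > cap ||
              mh < m - span || mh > m + span) {
            mh = m; sh = smom;
          }
          mu(l, j) = mh;
          sigma(l, j) = std::max(std::min(sh, cap), sigma_floor[j]);
        }
      } else {
        int k = ftype[j];
        LogicalMatrix adm = admiss[j];
        std::vector<double> cnt(k, 0.0);
        double tot = 0.0;
        for (int r : mem) {
          double v = Xreal(r, j);
          if (ISNAN(v)) continue;
          cnt[(int)v - 1] += 1.0; tot += 1.0;
        }
        int nadm = 0; for (int v = 0; v < k; ++v) if (adm(l, v)) ++nadm;
        double denom = tot + alpha * nadm;
        if (tot > 0.0 || (alpha > 0.0 && nadm > 0)) {
          for (int v = 0; v < k; ++v)
            cp[j](l, v) = adm(l, v) ? (cnt[v] + alpha) / denom : 0.0;
        } else {
          // no real non-missing values: global marginal restricted to the
          // admissible levels
          NumericVector g = marg_cat[j];
          double gs = 0.0;
          for (int v = 0; v < k; ++v) if (adm(l, v)) gs += g[v];
          for (int v = 0; v < k; ++v)
            cp[j](l, v) = (adm(l, v) && gs > 0) ? g[v] / gs : 0.0;
        }
        mu(l, j) = NA_REAL; sigma(l, j) = NA_REAL; emp_mean(l, j) = NA_REAL;
      }
    }
  }
  for (int j = 0; j < p; ++j) cat_probs[j] = (ftype[j] > 0) ? (SEXP)cp[j] : R_NilValue;
  return List::create(_["w"] = w, _["n_tl"] = n_tl, _["mu"] = mu,
                      _["sigma"] = sigma, _["emp_mean"] = emp_mean,
                      _["cat_probs"] = cat_probs);
}

// ---------------------------------------------------------------------------
// conditional mixture: adjusted weights, density, expectation, sampling

struct LeafModel {
  NumericMatrix lo, hi, mu, sigma, emp_mean;
  NumericVector w;
  IntegerVector ftype;
  std::vector<NumericMatrix> cat_probs;
  int L, p;
  explicit LeafModel(List m)
      : lo(as<NumericMatrix>(m["lo"])), hi(as<NumericMatrix>(m["hi"])),
        mu(as<NumericMatrix>(m["mu"])), sigma(as<NumericMatrix>(m["sigma"])),
        emp_mean(as<NumericMatrix>(m["emp_mean"])),
        w(as<NumericVector>(m["w"])), ftype(as<IntegerVector>(m["ftype"])) {
    List cpl = m["cat_probs"];
    for (int j = 0; j < (int)ftype.size(); ++j) {
      if (ftype[j] > 0) cat_probs.push_back(as<NumericMatrix>(cpl[j]));
      else cat_probs.push_back(NumericMatrix(0, 0));
    }
    L = lo.nrow(); p = lo.ncol();
  }
  // log density of observed value at leaf l, feature j; -Inf outside support
  double log_dens(int l, int j, double v) const {
    if (ftype[j] == 0) {
      double a = lo(l, j), b = hi(l, j);
      if (!(v > a && v <= b)) return R_NegInf;
      double s = sigma(l, j), m = mu(l, j);
      double lz = log_trunc_mass((a - m) / s, (b - m) / s);
      return R::dnorm(v, m, s, 1) - lz;
    }
    double pr = cat_probs[j](l, (int)v - 1);
    return pr > 0.0 ? std::log(pr) : R_NegInf;
  }
};

// log weights over leaves given evidence (NA entries of x are unobserved);
// returns unnormalized logw plus the log-sum-exp normalizer.
static void evidence_logw(const LeafModel& M, const NumericVector& x,
                          std::vector<double>& logw, double& logZ) {
  logw.assign(M.L, R_NegInf);
  double mx = R_NegInf;
  for (int l = 0; l < M.L; ++l) {
    if (M.w[l] <= 0.0) continue;
    double lw = std::log(M.w[l]);
    for (int j = 0; j < M.p && lw > R_NegInf; ++j) {
      if (ISNAN(x[j])) continue;
      lw += M.log_dens(l, j, x[j]);
    }
    logw[l] = lw;
    if (lw > mx) mx = lw;
  }
  if (mx == R_NegInf) { logZ = R_NegInf; return; }
  double s = 0.0;
  for (int l = 0; l < M.L; ++l)
    if (logw[l] > R_NegInf) s += std::exp(logw[l] - mx);
  logZ = mx + std::log(s);
}

// [[Rcpp::export]]
List cpp_adjust_weights(List model, NumericVector x) {
  LeafModel M(model);
  std::vector<double> logw;
  double logZ;
  evidence_logw(M, x, logw, logZ);
  NumericVector w(M.L);
  bool compatible = R_finite(logZ);
  if (compatible) {
    for (int l = 0; l < M.L; ++l)
      w[l] = logw[l] > R_NegInf ? std::exp(logw[l] - logZ) : 0.0;
  } else {
    for (int l = 0; l < M.L; ++l) w[l] = M.w[l];  // zero-mass fallback
  }
  return List::create(_["w"] = w, _["log_evidence"] = logZ,
                      _["compatible"] = compatible);
}

// Mixture log-density of complete rows (Eq. 2 of the leaf mixture).
// [[Rcpp::export]]
NumericVector cpp_mix_logdens(List model, NumericMatrix X) {
  LeafModel M(model);
  int n = X.nrow();
  NumericVector out(n);
  std::vector<double> logw;
  double logZ;
  for (int i = 0; i < n; ++i) {
    NumericVector x = X(i, _);
    evidence_logw(M, x, logw, logZ);
    out[i] = logZ;
  }
  return out;
}

static int draw_index(const std::vector<double>& prob) {
  double u = unif_rand(), c = 0.0;
  int last = -1;
  for (int i = 0; i < (int)prob.size(); ++i) {
    if (prob[i] <= 0.0) continue;
    last = i; c += prob[i];
    if (u <= c) return i;
  }
  return last;  // numerical slack
}

static double draw_truncnorm(double m, double s, double a, double b) {
  double pa = R::pnorm(a, m, s, 1, 0), pb = R::pnorm(b, m, s, 1, 0);
  double x;
  if (pb - pa > 1e-12) {
    double u = pa + unif_rand() * (pb - pa);
    x = R::qnorm(u, m, s, 1, 0);
  } else {
    // interval mass numerically nil: sample uniformly on the overlap of the
    // bounds with a +-6 sigma box around the mean (degenerate leaves)
    double aa = std::max(a, m - 6.0 * s), bb = std::min(b, m + 6.0 * s);
    if (!(bb > aa)) { aa = a; bb = b; }
    if (aa == R_NegInf) aa = bb - s;
    if (bb == R_PosInf) bb = aa + s;
    x = aa + unif_rand() * (bb - aa);
  }
  if (x <= a) x = std::nextafter(a, b);
  if (x > b) x = b;
  return x;
}

// Impute rows with missing entries from the conditional mixture.
// mode 0: conditional expectation (continuous) / weighted mode (categorical),
//         single completion.
// mode 1: m completions, each drawing one fresh leaf per row and sampling
//         every missing feature from that leaf.
// [[Rcpp::export]]
List cpp_impute_rows(List model, NumericMatrix X, int mode, int m,
                     NumericVector marg_mean, List marg_cat) {
  LeafModel M(model);
  int n = X.nrow(), p = X.ncol();
  int nout = (mode == 0) ? 1 : m;
  List out(nout);
  std::vector<NumericMatrix> mats;
  for (int q = 0; q < nout; ++q) mats.push_back(clone(X));
  int n_zero_mass = 0;

  std::vector<double> logw, prob(M.L);
  for (int i = 0; i < n; ++i) {
    bool has_na = false;
    for (int j = 0; j < p; ++j) if (ISNAN(X(i, j))) { has_na = true; break; }
    if (!has_na) continue;

    NumericVector x = X(i, _);
    double logZ;
    evidence_logw(M, x, logw, logZ);
    bool compatible = R_finite(logZ);
    if (!compatible) {
      ++n_zero_mass;
      for (int l = 0; l < M.L; ++l) prob[l] = M.w[l];
    } else {
      for (int l = 0; l < M.L; ++l)
        prob[l] = logw[l] > R_NegInf ? std::exp(logw[l] - logZ) : 0.0;
    }

    if (mode == 0) {
      for (int j = 0; j < p; ++j) {
        if (!ISNAN(X(i, j))) continue;
        if (M.ftype[j] == 0) {
          double e = 0.0;
          for (int l = 0; l < M.L; ++l) {
            if (prob[l] <= 0.0) continue;
            double mlj = M.emp_mean(l, j);
            if (ISNAN(mlj)) mlj = marg_mean[j];  // empty-leaf fallback
            e += prob[l] * mlj;
          }
          mats[0](i, j) = e;
        } else {
          int k = M.ftype[j];
          std::vector<double> score(k, 0.0);
          for (int l = 0; l < M.L; ++l) {
            if (prob[l] <= 0.0) continue;
            for (int v = 0; v < k; ++v) score[v] += prob[l] * M.cat_probs[j](l, v);
          }
          int bestv = 0;
          for (int v = 1; v < k; ++v) if (score[v] > score[bestv]) bestv = v;
          mats[0](i, j) = bestv + 1;  // ties -> lowest declared level
        }
      }
    } else {
      for (int q = 0; q < m; ++q) {
        int l = draw_index(prob);  // one fresh leaf per row per completion
        for (int j = 0; j < p; ++j) {
          if (!ISNAN(X(i, j))) continue;
          if (M.ftype[j] == 0) {
            mats[q](i, j) = draw_truncnorm(M.mu(l, j), M.sigma(l, j),
                                           M.lo(l, j), M.hi(l, j));
          } else {
            int k = M.ftype[j];
            std::vector<double> pr(k);
            double tot = 0.0;
            for (int v = 0; v < k; ++v) { pr[v] = M.cat_probs[j](l, v); tot += pr[v]; }
            if (tot <= 0.0) {  // leaf admits no non-NA level: global marginal
              NumericVector g = marg_cat[j];
              for (int v = 0; v < k; ++v) pr[v] = g[v];
            }
            mats[q](i, j) = draw_index(pr) + 1;
          }
        }
      }
    }
  }
  for (int q = 0; q < nout; ++q) out[q] = mats[q];
  return List::create(_["tables"] = out, _["n_zero_mass"] = n_zero_mass);
}
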