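// Numeric kernels: truncated-Gaussian density evaluation for the TFCR
// caller, an exact-greedy gradient-boosted regression-tree engine
// (squared loss, XGBoost-style leaf shrinkage), and path-dependent
// TreeSHAP attributions with the local-accuracy guarantee.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- KDE

// Density sum_i exp(-(x - c_i)^2 / (2 h^2)) on the grid from..to (step),
// kernels truncated at |x - c| > cutoff. centers must be sorted.
// [[Rcpp::export]]
NumericVector kde_profile_cpp(NumericVector centers, double from, double to,
                              double step, double h, double cutoff) {
  const int n = (int)std::floor((to - from) / step) + 1;
  NumericVector out(n);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  for (int i = 0; i < centers.size(); ++i) {
    const double c = centers[i];
    // grid indices within the truncation window of this center
    int j0 = (int)std::ceil((c - cutoff - from) / step);
    int j1 = (int)std::floor((c + cutoff - from) / step);
    if (j0 < 0) j0 = 0;
    if (j1 > n - 1) j1 = n - 1;
    for (int j = j0; j <= j1; ++j) {
      const double d = from + j * step - c;
      out[j] += std::exp(-d * d * inv2h2);
    }
  }
  return out;
}

// ------------------------------------------------------------ trees

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left iff x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf value (0 for internal)
  std::vector<double> cover;     // training rows reaching the node
};

static List tree_to_list(const Tree &t) {
  return List::create(
      _["feature"] = wrap(t.feature), _["threshold"] = wrap(t.threshold),
      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
      _["value"] = wrap(t.value), _["cover"] = wrap(t.cover));
}

static Tree tree_from_list(const List &l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  t.cover = as<std::vector<double>>(l["cover"]);
  return t;
}

static double predict_tree(const Tree &t, const double *x, int ncol_stride,
                           const NumericMatrix &X, int row) {
  (void)x; (void)ncol_stride;
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  }
  return t.value[node];
}

struct GrowCtx {
  const NumericMatrix *X;
  const std::vector<double> *grad; // residuals (negative gradient)
  double l2;
  int max_depth;
  int min_child;
  const std::vector<int> *feats; // candidate features for this tree
  Tree *tree;
};

static int grow_node(GrowCtx &ctx, std::vector<int> &rows, int depth) {
  Tree &t = *ctx.tree;
  const int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(0.0);
  t.cover.push_back((double)rows.size());

  double G = 0.0;
  for (int r : rows) G += (*ctx.grad)[r];
  const double N = (double)rows.size();
  const double parent_score = G * G / (N + ctx.l2);

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  if (depth < ctx.max_depth && (int)rows.size() >= 2 * ctx.min_child) {
    std::vector<std::pair<double, double>> vals; // (x, grad)
    for (int f : *ctx.feats) {
      vals.clear();
      vals.reserve(rows.size());
      bool binary = true;
      for (int r : rows) {
        double v = (*ctx.X)(r, f);
        if (v != 0.0 && v != 1.0) binary = false;
        vals.push_back({v, (*ctx.grad)[r]});
      }
      if (binary) {
        double GL = 0.0; int NL = 0;
        for (auto &p : vals)
          if (p.first <= 0.5) { GL += p.second; ++NL; }
        int NR = (int)rows.size() - NL;
        if (NL >= ctx.min_child && NR >= ctx.min_child) {
          double GR = G - GL;
          double gain = GL * GL / (NL + ctx.l2) + GR * GR / (NR + ctx.l2) -
                        parent_score;
          if (gain > best_gain) {
            best_gain = gain; best_feat = f; best_thr = 0.5;
          }
        }
      } else {
        std::sort(vals.begin(), vals.end());
        double GL = 0.0;
        for (int i = 0; i + 1 < (int)vals.size(); ++i) {
          GL += vals[i].second;
          if (vals[i].first == vals[i + 1].first) continue;
          int NL = i + 1, NR = (int)vals.size() - NL;
          if (NL < ctx.min_child || NR < ctx.min_child) continue;
          double GR = G - GL;
          double gain = GL * GL / (NL + ctx.l2) + GR * GR / (NR + ctx.l2) -
                        parent_score;
          if (gain > best_gain) {
            best_gain = gain; best_feat = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }
  }

  if (best_feat < 0) {
    t.value[node] = G / (N + ctx.l2);
    return node;
  }
  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if ((*ctx.X)(r, best_feat) <= best_thr) lrows.push_back(r);
    else rrows.push_back(r);
  }
  t.feature[node] = best_feat;
  t.threshold[node] = best_thr;
  std::vector<int>().swap(rows); // free before recursing
  int li = grow_node(ctx, lrows, depth + 1);
  int ri = grow_node(ctx, rrows, depth + 1);
  t.left[node] = li;
  t.right[node] = ri;
  return node;
}

// Fit a gradient-boosted forest to y with squared loss.
// Returns list(trees = list of trees, base_score = double).
// [[Rcpp::export]]
List fit_gbt_cpp(NumericMatrix X, NumericVector y, int n_iter, double lr,
                 int max_depth, double l2, double subsample, double colsample,
                 int min_child, int seed) {
  const int n = X.nrow(), p = X.ncol();
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;
  std::vector<double> pred(n, base), grad(n);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  List trees(n_iter);
  std::vector<int> all_feats(p);
  for (int f = 0; f < p; ++f) all_feats[f] = f;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) grad[i] = y[i] - pred[i];
    // Bernoulli row subsample
    std::vector<int> rows;
    rows.reserve(n);
    if (subsample >= 1.0) {
      rows.resize(n);
      for (int i = 0; i < n; ++i) rows[i] = i;
    } else {
      for (int i = 0; i < n; ++i)
        if (unif(rng) < subsample) rows.push_back(i);
      if ((int)rows.size() < 2 * min_child) {
        rows.resize(n);
        for (int i = 0; i < n; ++i) rows[i] = i;
      }
    }
    // column subsample per tree
    std::vector<int> feats;
    if (colsample >= 1.0) {
      feats = all_feats;
    } else {
      int k = std::max(1, (int)std::round(colsample * p));
      std::vector<int> perm = all_feats;
      std::shuffle(perm.begin(), perm.end(), rng);
      feats.assign(perm.begin(), perm.begin() + k);
      std::sort(feats.begin(), feats.end());
    }
    Tree t;
    GrowCtx ctx{&X, &grad, l2, max_depth, min_child, &feats, &t};
    std::vector<int> r2 = rows;
    grow_node(ctx, r2, 0);
    for (int i = 0; i < n; ++i)
      pred[i] += lr * predict_tree(t, nullptr, 0, X, i);
    trees[it] = tree_to_list(t);
  }
  return List::create(_["trees"] = trees, _["base_score"] = base);
}

// Predict sum of base + sum_t w_t * tree_t(x).
// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X,
                                 double base_score,
                                 NumericVector tree_weights) {
  const int n = X.nrow(), T = trees.size();
  std::vector<Tree> ts(T);
  for (int t = 0; t < T; ++t) ts[t] = tree_from_list(trees[t]);
  NumericVector out(n, base_score);
  for (int t = 0; t < T; ++t) {
    const double w = tree_weights[t];
    for (int i = 0; i < n; ++i)
      out[i] += w * predict_tree(ts[t], nullptr, 0, X, i);
  }
  return out;
}

// ---------------------------------------------------------- TreeSHAP

struct PathElem {
  int d;       // feature index (-1 for the root placeholder)
  double z;    // fraction of zero (cold) paths
  double o;    // fraction of one (hot) paths
  double w;    // permutation weight
};

static void extend_path(std::vector<PathElem> &m, double pz, double po,
                        int pi) {
  const int l = (int)m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PathElem> &m, int i) {
  const int l = (int)m.size() - 1;
  const double o = m[i].o, z = m[i].z;
  double nxt = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0.0) {
      const double tmp = m[j].w;
      m[j].w = nxt * (l + 1) / (double)((j + 1) * o);
      nxt = tmp - m[j].w * z * (l - j) / (double)(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (double)(z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_sum(const std::vector<PathElem> &m, int i) {
  const int l = (int)m.size() - 1;
  const double o = m[i].o, z = m[i].z;
  double total = 0.0;
  if (o != 0.0) {
    double nxt = m[l].w;
    for (int j = l - 1; j >= 0; --j) {
      const double tmp = nxt * (l + 1) / (double)((j + 1) * o);
      total += tmp;
      nxt = m[j].w - tmp * z * (l - j) / (double)(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      total += m[j].w * (l + 1) / (double)(z * (l - j));
  }
  return total;
}

static void shap_recurse(const Tree &t, const NumericMatrix &X, int row,
                         double *phi, int node, std::vector<PathElem> m,
                         double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (t.feature[node] < 0) {
    for (int i = 1; i < (int)m.size(); ++i) {
      const double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * t.value[node];
    }
    return;
  }
  const int f = t.feature[node];
  const int hot = (X(row, f) <= t.threshold[node]) ? t.left[node]
                                                   : t.right[node];
  const int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i)
    if (m[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    unwind_path(m, k);
  }
  const double rj = t.cover[node];
  shap_recurse(t, X, row, phi, hot, m, iz * t.cover[hot] / rj, io, f);
  shap_recurse(t, X, row, phi, cold, m, iz * t.cover[cold] / rj, 0.0, f);
}

// Cover-weighted expected leaf value of a tree.
static double tree_expected(const Tree &t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  const double wl = t.cover[t.left[node]], wr = t.cover[t.right[node]];
  return (wl * tree_expected(t, t.left[node]) +
          wr * tree_expected(t, t.right[node])) / (wl + wr);
}

// Path-dependent TreeSHAP for a weighted forest. Returns
// list(phi = n x p matrix, base = scalar expected prediction).
// [[Rcpp::export]]
List treeshap_cpp(List trees, NumericMatrix X, double base_score,
                  NumericVector tree_weights) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  std::vector<Tree> ts(T);
  for (int t = 0; t < T; ++t) ts[t] = tree_from_list(trees[t]);
  NumericMatrix phi(n, p);
  double base = base_score;
  for (int t = 0; t < T; ++t) base += tree_weights[t] * tree_expected(ts[t], 0);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      std::vector<double> tphi(p, 0.0);
      std::vector<PathElem> m;
      m.reserve(32);
      shap_recurse(ts[t], X, i, tphi.data(), 0, m, 1.0, 1.0, -1);
      for (int f = 0; f < p; ++f) buf[f] += tree_weights[t] * tphi[f];
    }
    for (int f = 0; f < p; ++f) phi(i, f) = buf[f];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
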