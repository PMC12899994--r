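// Exact TreeSHAP in double precision over an explicit tree-ensemble
// structure (polynomial-time path-dependent algorithm). Computing the
// attributions and the margin from the same double-precision traversal
// makes the additivity identity base + sum(phi) == margin hold to
// machine precision, which float32 library implementations cannot
// guarantee for deep ensembles.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Tree {
  IntegerVector left, right, def, feature;
  NumericVector thresh, value, cover;
};

// xgboost evaluates splits in float32; replicate its comparison so the
// traversal (and hence the attributions) matches the booster exactly.
static inline bool goes_left(double xv, double thresh) {
  return (float)xv < (float)thresh;
}

struct PathElement {
  int d;        // feature index of the split that created this element
  double z;     // fraction of "zero" (cold) paths flowing through
  double o;     // fraction of "one" (hot) paths flowing through
  double w;     // permutation weight
};

static void extend_path(std::vector<PathElement>& m, double pz, double po,
                        int pi) {
  int l = (int)m.size();
  PathElement e;
  e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PathElement>& m, int i) {
  int l = (int)m.size() - 1;
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (m[i].o != 0.0) {
      double t = m[j].w;
      m[j].w = n * (l + 1) / (double)((j + 1) * m[i].o);
      n = t - m[j].w * m[i].z * (l - j) / (double)(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (m[i].z * (double)(l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d; m[j].z = m[j + 1].z; m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_sum(const std::vector<PathElement>& m, int i) {
  int l = (int)m.size() - 1;
  double total = 0.0;
  if (m[i].o != 0.0) {
    double n = m[l].w;
    for (int j = l - 1; j >= 0; --j) {
      double tmp = n / ((j + 1) * m[i].o);
      total += tmp;
      n = m[j].w - tmp * m[i].z * (l - j);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      total += m[j].w / (m[i].z * (double)(l - j));
    }
  }
  return total * (l + 1);
}

static void tree_recurse(const Tree& T, int node,
                         std::vector<PathElement> m, double pz, double po,
                         int pi, const double* x, std::vector<double>& phi) {
  extend_path(m, pz, po, pi);
  if (T.feature[node] < 0) {            // leaf
    for (int i = 1; i < (int)m.size(); ++i) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * T.value[node];
    }
    return;
  }
  int f = T.feature[node];
  double xv = x[f];
  int hot;
  if (ISNAN(xv)) hot = T.def[node];
  else hot = goes_left(xv, T.thresh[node]) ? T.left[node] : T.right[node];
  int cold = (hot == T.left[node]) ? T.right[node] : T.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) {
    if (m[i].d == f) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    unwind_path(m, k);
  }
  double rj = T.cover[node];
  tree_recurse(T, hot, m, iz * T.cover[hot] / rj, io, f, x, phi);
  tree_recurse(T, cold, m, iz * T.cover[cold] / rj, 0.0, f, x, phi);
}

static Tree as_tree(List t) {
  Tree T;
  T.left = t["left"]; T.right = t["right"]; T.def = t["def"];
  T.feature = t["feature"]; T.thresh = t["thresh"];
  T.value = t["value"]; T.cover = t["cover"];
  return T;
}

static double tree_expected(const Tree& T, int node) {
  if (T.feature[node] < 0) return T.value[node];
  return (T.cover[T.left[node]] * tree_expected(T, T.left[node]) +
          T.cover[T.right[node]] * tree_expected(T, T.right[node])) /
         T.cover[node];
}

// Returns [n_samples x (n_features + 1)]: per-feature contributions plus
// the bias (cover-weighted expected margin) in the last column.
// [[Rcpp::export]]
NumericMatrix treeshap_cpp(NumericMatrix X, List trees) {
  int n = X.nrow(), M = X.ncol(), nt = trees.size();
  std::vector<Tree> Ts(nt);
  double bias = 0.0;
  for (int t = 0; t < nt; ++t) {
    Ts[t] = as_tree(trees[t]);
    bias += tree_expected(Ts[t], 0);
  }
  NumericMatrix out(n, M + 1);
  std::vector<double> xrow(M), phi(M);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < M; ++j) xrow[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int t = 0; t < nt; ++t) {
      std::vector<PathElement> m;
      m.reserve(16);
      tree_recurse(Ts[t], 0, m, 1.0, 1.0, -1, xrow.data(), phi);
    }
    for (int j = 0; j < M; ++j) out(i, j) = phi[j];
    out(i, M) = bias;
  }
  return out;
}

// Margin predictions by double-precision traversal of the same trees.
// [[Rcpp::export]]
NumericVector tree_margin_cpp(NumericMatrix X, List trees,
                              double base_margin) {
  int n = X.nrow(), nt = trees.size();
  std::vector<Tree> Ts(nt);
  for (int t = 0; t < nt; ++t) Ts[t] = as_tree(trees[t]);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = base_margin;
    for (int t = 0; t < nt; ++t) {
      const Tree& T = Ts[t];
      int node = 0;
      while (T.feature[node] >= 0) {
        double xv = X(i, T.feature[node]);
        if (ISNAN(xv)) node = T.def[node];
        else node = goes_left(xv, T.thresh[node]) ? T.left[node]
                                                  : T.right[node];
      }
      s += T.value[node];
    }
    out[i] = s;
  }
  return out;
}
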