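#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Path-dependent TreeSHAP over a parsed boosted-tree ensemble.
//
// Each tree is passed as parallel arrays (0-based node indices):
//   feature[i]  split feature index, -1 for a leaf
//   split[i]    split threshold (x < split goes to `yes`)
//   yes[i], no[i], missing[i]  child node indices (-1 for leaves)
//   value[i]    leaf output (0 for internal nodes)
//   cover[i]    node weight (sum of hessians recorded by the learner)
//
// All arithmetic is double precision, so base + sum(phi) reproduces the
// ensemble margin to machine precision (the additivity contract).

struct PathElem {
  int d;        // feature index entering the path (-1 for the root sentinel)
  double z;     // fraction of zero (feature-missing) paths flowing through
  double o;     // fraction of one (feature-present) paths flowing through
  double w;     // permutation weight
};

struct Tree {
  const int *feature, *yes, *no_, *missing;
  const double *split, *value, *cover;
};

static void extend_path(std::vector<PathElem> &m, double pz, double po, int pi) {
  const int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

static void unwind_path(std::vector<PathElem> &m, int i) {
  const int l = static_cast<int>(m.size()) - 1;
  const double o = m[i].o, z = m[i].z;
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0) {
      const double tmp = m[j].w;
      m[j].w = n * (l + 1) / static_cast<double>((j + 1) * o);
      n = tmp - m[j].w * z * (l - j) / static_cast<double>(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (z * static_cast<double>(l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_path_sum(const std::vector<PathElem> &m, int i) {
  const int l = static_cast<int>(m.size()) - 1;
  const double o = m[i].o, z = m[i].z;
  double n = m[l].w, total = 0.0;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0) {
      const double tmp = n * (l + 1) / static_cast<double>((j + 1) * o);
      total += tmp;
      n = m[j].w - tmp * z * (l - j) / static_cast<double>(l + 1);
    } else {
      total += (m[j].w / z) * (l + 1) / static_cast<double>(l - j);
    }
  }
  return total;
}

// xgboost compares in single precision; mirror that for identical routing
static inline bool goes_left(double x, double split) {
  return static_cast<float>(x) < static_cast<float>(split);
}

static void tree_shap_recurse(const Tree &t, const double *x, double *phi,
                              int node, std::vector<PathElem> m,
                              double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (t.feature[node] < 0) {  // leaf
    const double v = t.value[node];
    for (int i = 1; i < static_cast<int>(m.size()); ++i)
      phi[m[i].d] += unwound_path_sum(m, i) * (m[i].o - m[i].z) * v;
    return;
  }
  const int f = t.feature[node];
  const double xf = x[f];
  int hot, cold;
  if (ISNAN(xf)) {
    hot = t.missing[node];
  } else {
    hot = goes_left(xf, t.split[node]) ? t.yes[node] : t.no_[node];
  }
  cold = (hot == t.yes[node]) ? t.no_[node] : t.yes[node];
  const double w = t.cover[node];
  const double hot_z = t.cover[hot] / w;
  const double cold_z = t.cover[cold] / w;
  double iz = 1.0, io = 1.0;
  for (int i = 1; i < static_cast<int>(m.size()); ++i) {
    if (m[i].d == f) {
      iz = m[i].z;
      io = m[i].o;
      unwind_path(m, i);
      break;
    }
  }
  tree_shap_recurse(t, x, phi, hot, m, hot_z * iz, io, f);
  tree_shap_recurse(t, x, phi, cold, m, cold_z * iz, 0.0, f);
}

static double tree_expected_value(const Tree &t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  const double w = t.cover[node];
  return (t.cover[t.yes[node]] * tree_expected_value(t, t.yes[node]) +
          t.cover[t.no_[node]] * tree_expected_value(t, t.no_[node])) / w;
}

static double tree_leaf_value(const Tree &t, const double *x) {
  int node = 0;
  while (t.feature[node] >= 0) {
    const double xf = x[t.feature[node]];
    if (ISNAN(xf))
      node = t.missing[node];
    else
      node = goes_left(xf, t.split[node]) ? t.yes[node] : t.no_[node];
  }
  return t.value[node];
}

static std::vector<Tree> unpack_trees(const List &trees) {
  std::vector<Tree> out;
  out.reserve(trees.size());
  for (int k = 0; k < trees.size(); ++k) {
    List tr = trees[k];
    IntegerVector feature = tr["feature"], yes = tr["yes"], no_ = tr["no"],
                  missing = tr["missing"];
    NumericVector split = tr["split"], value = tr["value"], cover = tr["cover"];
    out.push_back({feature.begin(), yes.begin(), no_.begin(), missing.begin(),
                   split.begin(), value.begin(), cover.begin()});
  }
  return out;
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> tv = unpack_trees(trees);

  double base = 0.0;
  for (const Tree &t : tv) base += tree_expected_value(t, 0);

  NumericMatrix phi(n, p);
  NumericVector margin(n);
  std::vector<double> x(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    double *phirow = new double[p]();
    double marg = 0.0;
    for (const Tree &t : tv) {
      std::vector<PathElem> m;
      m.reserve(16);
      tree_shap_recurse(t, x.data(), phirow, 0, m, 1.0, 1.0, -1);
      marg += tree_leaf_value(t, x.data());
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
    margin[i] = marg;
    delete[] phirow;
  }
  return List::create(_["phi"] = phi, _["base"] = base, _["margin"] = margin);
}

// [[Rcpp::export(name = ".tree_margin_cpp")]]
NumericVector tree_margin_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> tv = unpack_trees(trees);
  NumericVector margin(n);
  std::vector<double> x(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    double marg = 0.0;
    for (const Tree &t : tv) marg += tree_leaf_value(t, x.data());
    margin[i] = marg;
  }
  return margin;
}
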