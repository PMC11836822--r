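// Path-dependent TreeSHAP for binary decision trees.
//
// Implements the polynomial-time Shapley value algorithm for tree
// ensembles: for each instance the recursion keeps the set of features on
// the current decision path together with the fraction of "one" (feature
// known) and "zero" (feature marginalised by cover) subsets flowing down,
// and reads off each feature's contribution at the leaves. Covers are the
// training-sample counts per node, supplied by the caller.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElem {
  int d;        // feature index of the split that created this element
  double z;     // fraction of zero paths flowing through
  double o;     // fraction of one paths flowing through
  double w;     // proportion of subsets of each cardinality
};

static void extend_path(std::vector<PathElem>& m, double pz, double po,
                        int pi) {
  int l = (int)m.size();
  PathElem e; e.d = pi; e.z = pz; e.o = po; e.w = (l == 0 ? 1.0 : 0.0);
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PathElem>& m, int i) {
  int l = (int)m.size() - 1;
  double n = m[l].w;
  double o = m[i].o, z = m[i].z;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0.0) {
      double t = m[j].w;
      m[j].w = n * (l + 1) / (double)((j + 1) * o);
      n = t - m[j].w * z * (l - j) / (double)(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (double)(z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d; m[j].z = m[j + 1].z; m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_sum(const std::vector<PathElem>& m, int i) {
  int l = (int)m.size() - 1;
  double o = m[i].o, z = m[i].z;
  double sum = 0.0, n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0.0) {
      double t = n * (l + 1) / (double)((j + 1) * o);
      sum += t;
      n = m[j].w - t * z * (l - j) / (double)(l + 1);
    } else {
      sum += m[j].w * (l + 1) / (double)(z * (l - j));
    }
  }
  return sum;
}

struct Tree {
  const int* left; const int* right; const int* feat;
  const double* thr; const double* cover; const double* value;
};

static void tree_recurse(const Tree& t, const double* x, double* phi,
                         int node, std::vector<PathElem> m,
                         double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (t.feat[node] < 0) {  // leaf
    double v = t.value[node];
    for (size_t i = 1; i < m.size(); ++i) {
      phi[m[i].d] += unwound_sum(m, (int)i) * (m[i].o - m[i].z) * v;
    }
    return;
  }
  int f = t.feat[node];
  int hot = (x[f] <= t.thr[node]) ? t.left[node] : t.right[node];
  int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (size_t i = 1; i < m.size(); ++i) {
    if (m[i].d == f) { k = (int)i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    unwind_path(m, k);
  }
  double ch = t.cover[hot] / t.cover[node];
  double cc = t.cover[cold] / t.cover[node];
  tree_recurse(t, x, phi, hot, m, iz * ch, io, f);
  tree_recurse(t, x, phi, cold, m, iz * cc, 0.0, f);
}

// trees: list of lists with elements left, right, feature (int, -1 = leaf),
// threshold, cover (double), value (double, per explained class).
// X: instances in rows. Returns matrix n x p of per-feature attributions.
// [[Rcpp::export]]
NumericMatrix treeshap_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), nt = trees.size();
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p);
  for (int it = 0; it < nt; ++it) {
    List tr = trees[it];
    IntegerVector left = tr["left"], right = tr["right"], feat = tr["feature"];
    NumericVector thr = tr["threshold"], cov = tr["cover"], val = tr["value"];
    Tree t;
    t.left = left.begin(); t.right = right.begin(); t.feat = feat.begin();
    t.thr = thr.begin(); t.cover = cov.begin(); t.value = val.begin();
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::vector<double> ph(p, 0.0);
      std::vector<PathElem> m;
      m.reserve(64);
      tree_recurse(t, xrow.data(), ph.data(), 0, m, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += ph[j];
    }
  }
  // average over trees (ensemble prediction is the mean of tree outputs)
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= nt;
  return phi;
}
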