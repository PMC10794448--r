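// Gradient-boosted regression trees (squared-error boosting on CART trees)
// with exact path-dependent TreeSHAP attribution.
//
// No gradient-boosting or SHAP library ships with the target environment,
// so the booster itself lives here: greedy variance-reduction splits on
// presorted feature indices, residual fitting with shrinkage, and the
// polynomial-time TreeSHAP recursion over the (cover-weighted) tree paths.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold; // go left iff x < threshold
  std::vector<int> left, right;
  std::vector<double> value;     // mean residual in node
  std::vector<double> cover;     // training sample count
  int add() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    cover.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct Builder {
  const double* X; // column-major n x p
  const double* y; // residuals
  double lambda;   // L2 leaf regularization (unit hessian per sample)
  int n, p, maxDepth, minLeaf;
  std::vector<std::vector<int>> sorted; // per feature, node-partitioned order
  std::vector<char> goLeft;
  std::vector<int> buf;
  TreeNodes tree;

  double col(int i, int f) const { return X[(size_t)f * n + i]; }

  int build(int lo, int hi, int depth) {
    const int node = tree.add();
    const int m = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    const std::vector<int>& idx0 = sorted[0];
    for (int t = lo; t < hi; ++t) {
      const double v = y[idx0[t]];
      sum += v;
      sumsq += v * v;
    }
    tree.value[node] = sum / (m + lambda);
    tree.cover[node] = m;
    const double totalScore = sum * sum / (m + lambda);
    if (depth >= maxDepth || m < 2 * minLeaf ||
        sumsq - sum * sum / m < 1e-12 * std::max(1.0, sumsq))
      return node;

    double bestGain = 1e-12;
    int bestF = -1, bestNL = 0;
    double bestThr = 0.0;
    for (int f = 0; f < p; ++f) {
      const std::vector<int>& idx = sorted[f];
      double sl = 0.0;
      for (int t = lo; t < hi - 1; ++t) {
        sl += y[idx[t]];
        const int nl = t - lo + 1, nr = m - nl;
        if (nl < minLeaf || nr < minLeaf) continue;
        const double xa = col(idx[t], f), xb = col(idx[t + 1], f);
        if (xa >= xb) continue; // no split between tied values
        const double sr = sum - sl;
        const double gain =
            sl * sl / (nl + lambda) + sr * sr / (nr + lambda) - totalScore;
        if (gain > bestGain) {
          bestGain = gain;
          bestF = f;
          bestNL = nl;
          bestThr = xa + (xb - xa) / 2.0;
        }
      }
    }
    if (bestF < 0) return node;

    for (int t = lo; t < hi; ++t) {
      const int i = sorted[bestF][t];
      goLeft[i] = col(i, bestF) < bestThr ? 1 : 0;
    }
    // stable partition of every feature's order within [lo, hi)
    for (int f = 0; f < p; ++f) {
      std::vector<int>& idx = sorted[f];
      int nl = 0, nr = 0;
      for (int t = lo; t < hi; ++t) {
        const int i = idx[t];
        if (goLeft[i])
          idx[lo + nl++] = i;
        else
          buf[nr++] = i;
      }
      for (int t = 0; t < nr; ++t) idx[lo + nl + t] = buf[t];
    }

    tree.feature[node] = bestF;
    tree.threshold[node] = bestThr;
    tree.left[node] = build(lo, lo + bestNL, depth + 1);
    tree.right[node] = build(lo + bestNL, hi, depth + 1);
    return node;
  }
};

NumericMatrix packTree(const TreeNodes& t) {
  const int k = (int)t.feature.size();
  NumericMatrix m(k, 6);
  for (int i = 0; i < k; ++i) {
    m(i, 0) = t.feature[i];
    m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
    m(i, 5) = t.cover[i];
  }
  colnames(m) =
      CharacterVector::create("feature", "threshold", "left", "right",
                              "value", "cover");
  return m;
}

double predictTree(const NumericMatrix& t, const double* X, int n, int i) {
  int node = 0;
  while ((int)t(node, 0) >= 0) {
    const int f = (int)t(node, 0);
    node = X[(size_t)f * n + i] < t(node, 1) ? (int)t(node, 2)
                                             : (int)t(node, 3);
  }
  return t(node, 4);
}

// ---- TreeSHAP (path-dependent, exact) --------------------------------------

struct PathElem {
  int d;
  double z, o, w;
};

void extendPath(std::vector<PathElem>& m, double pz, double po, int pi) {
  const int l = (int)m.size();
  PathElem e;
  e.d = pi;
  e.z = pz;
  e.o = po;
  e.w = l == 0 ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1.0) / (l + 1.0);
    m[i].w = pz * m[i].w * (l - i) / (l + 1.0);
  }
}

void unwindPath(std::vector<PathElem>& m, int pathIndex) {
  const int ud = (int)m.size() - 1;
  const double oneFr = m[pathIndex].o;
  const double zeroFr = m[pathIndex].z;
  double nxt = m[ud].w;
  for (int i = ud - 1; i >= 0; --i) {
    if (oneFr != 0.0) {
      const double tmp = m[i].w;
      m[i].w = nxt * (ud + 1.0) / ((i + 1.0) * oneFr);
      nxt = tmp - m[i].w * zeroFr * (ud - i) / (ud + 1.0);
    } else {
      m[i].w = m[i].w * (ud + 1.0) / (zeroFr * (ud - i));
    }
  }
  for (int i = pathIndex; i < ud; ++i) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
  m.pop_back();
}

double unwoundSum(const std::vector<PathElem>& m, int pathIndex) {
  const int ud = (int)m.size() - 1;
  const double oneFr = m[pathIndex].o;
  const double zeroFr = m[pathIndex].z;
  double nxt = m[ud].w, total = 0.0;
  for (int i = ud - 1; i >= 0; --i) {
    if (oneFr != 0.0) {
      const double tmp = nxt * (ud + 1.0) / ((i + 1.0) * oneFr);
      total += tmp;
      nxt = m[i].w - tmp * zeroFr * (ud - i) / (ud + 1.0);
    } else {
      total += m[i].w / zeroFr * (ud + 1.0) / (ud - i);
    }
  }
  return total;
}

void shapRecurse(const NumericMatrix& t, const double* X, int n, int row,
                 double* phi, int node, std::vector<PathElem> m, double pz,
                 double po, int pi) {
  extendPath(m, pz, po, pi);
  const int f = (int)t(node, 0);
  if (f < 0) {
    for (int i = 1; i < (int)m.size(); ++i) {
      const double w = unwoundSum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * t(node, 4);
    }
    return;
  }
  const double x = X[(size_t)f * n + row];
  int hot = (int)t(node, 2), cold = (int)t(node, 3);
  if (!(x < t(node, 1))) std::swap(hot, cold);
  double iz = 1.0, io = 1.0;
  int k = 1;
  for (; k < (int)m.size(); ++k)
    if (m[k].d == f) break;
  if (k < (int)m.size()) {
    iz = m[k].z;
    io = m[k].o;
    unwindPath(m, k);
  }
  const double cv = t(node, 5);
  shapRecurse(t, X, n, row, phi, hot, m, iz * t(hot, 5) / cv, io, f);
  shapRecurse(t, X, n, row, phi, cold, m, iz * t(cold, 5) / cv, 0.0, f);
}

double treeExpectation(const NumericMatrix& t, int node) {
  if ((int)t(node, 0) < 0) return t(node, 4);
  const int l = (int)t(node, 2), r = (int)t(node, 3);
  return (t(l, 5) * treeExpectation(t, l) + t(r, 5) * treeExpectation(t, r)) /
         t(node, 5);
}

} // namespace

// [[Rcpp::export(name = ".gbtFitCpp")]]
List gbtFitCpp(NumericMatrix X, NumericVector y, int nEstimators,
               int maxDepth, double eta, int minLeaf, double lambda) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("empty training set");
  const double base =
      std::accumulate(y.begin(), y.end(), 0.0) / (double)n;

  // master presort of every feature column (stable: ties keep row order)
  std::vector<std::vector<int>> master(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int>& idx = master[f];
    for (int i = 0; i < n; ++i) idx[i] = i;
    const double* cx = &X[0] + (size_t)f * n;
    std::stable_sort(idx.begin(), idx.end(),
                     [cx](int a, int b) { return cx[a] < cx[b]; });
  }

  std::vector<double> pred(n, base), resid(n);
  List trees(nEstimators);
  Builder b;
  b.X = &X[0];
  b.n = n;
  b.p = p;
  b.maxDepth = maxDepth;
  b.minLeaf = minLeaf;
  b.lambda = lambda;
  b.goLeft.assign(n, 0);
  b.buf.assign(n, 0);
  for (int it = 0; it < nEstimators; ++it) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    b.y = resid.data();
    b.sorted = master; // reset node partitioning
    b.tree = TreeNodes();
    b.build(0, n, 0);
    NumericMatrix tm = packTree(b.tree);
    trees[it] = tm;
    for (int i = 0; i < n; ++i)
      pred[i] += eta * predictTree(tm, &X[0], n, i);
  }
  return List::create(_["trees"] = trees, _["base"] = base,
                      _["eta"] = eta, _["p"] = p);
}

// [[Rcpp::export(name = ".gbtPredictCpp")]]
NumericVector gbtPredictCpp(List trees, double base, double eta,
                            NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int k = 0; k < trees.size(); ++k) {
    NumericMatrix t = trees[k];
    for (int i = 0; i < n; ++i) out[i] += eta * predictTree(t, &X[0], n, i);
  }
  return out;
}

// [[Rcpp::export(name = ".gbtShapCpp")]]
List gbtShapCpp(List trees, double base, double eta, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double expected = base;
  std::vector<double> rowPhi(p);
  for (int k = 0; k < trees.size(); ++k) {
    NumericMatrix t = trees[k];
    expected += eta * treeExpectation(t, 0);
    for (int i = 0; i < n; ++i) {
      std::fill(rowPhi.begin(), rowPhi.end(), 0.0);
      std::vector<PathElem> m;
      shapRecurse(t, &X[0], n, i, rowPhi.data(), 0, m, 1.0, 1.0, -1);
      for (int f = 0; f < p; ++f) phi(i, f) += eta * rowPhi[f];
    }
  }
  return List::create(_["phi"] = phi, _["expected"] = expected);
}
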