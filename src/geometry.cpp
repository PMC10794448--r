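// Hot polygon primitives: ray casting against contour boundaries and
// point-in-polygon tests. Invalid configurations are reported with NA
// sentinels; the R layer raises classed conditions.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Distances from origin to the polygon boundary along each direction.
// firstOnly: nearest crossing (NA if none). Otherwise requires exactly one
// distinct crossing (vertex-grazing duplicates collapsed), NA otherwise.
// [[Rcpp::export(name = ".rayCastCpp")]]
NumericVector rayCastCpp(NumericMatrix pts, NumericVector origin,
                         NumericVector angles, bool firstOnly) {
  const int n = pts.nrow(), na = angles.size();
  std::vector<double> ex(n), ey(n), bx(n), by(n);
  for (int j = 0; j < n; ++j) {
    const int k = (j + 1) % n;
    ex[j] = pts(k, 0) - pts(j, 0);
    ey[j] = pts(k, 1) - pts(j, 1);
    bx[j] = pts(j, 0) - origin[0];
    by[j] = pts(j, 1) - origin[1];
  }
  NumericVector out(na);
  std::vector<double> hits;
  for (int a = 0; a < na; ++a) {
    const double dx = std::cos(angles[a]), dy = std::sin(angles[a]);
    hits.clear();
    double tmin = R_PosInf;
    for (int j = 0; j < n; ++j) {
      const double dxe = dx * ey[j] - dy * ex[j];
      if (dxe == 0.0) continue;
      const double t = (bx[j] * ey[j] - by[j] * ex[j]) / dxe;
      const double s = (dy * bx[j] - dx * by[j]) / dxe;
      if (t > 1e-12 && s > -1e-9 && s < 1.0 + 1e-9) {
        if (firstOnly) {
          if (t < tmin) tmin = t;
        } else {
          hits.push_back(t);
        }
      }
    }
    if (firstOnly) {
      out[a] = std::isfinite(tmin) ? tmin : NA_REAL;
    } else {
      std::sort(hits.begin(), hits.end());
      int distinct = 0;
      double last = -1.0, keep = NA_REAL;
      for (size_t h = 0; h < hits.size(); ++h) {
        if (distinct == 0 || hits[h] - last > 1e-9 * (1.0 + last)) {
          ++distinct;
          keep = hits[h];
        }
        last = hits[h];
      }
      out[a] = distinct == 1 ? keep : NA_REAL;
    }
  }
  return out;
}

// Even-odd point-in-polygon for many points; points within tol of the
// boundary count as inside.
// [[Rcpp::export(name = ".pointsInPolyCpp")]]
LogicalVector pointsInPolyCpp(NumericMatrix P, NumericMatrix poly,
                              double tol) {
  const int m = P.nrow(), n = poly.nrow();
  std::vector<double> x(n), y(n), xn(n), yn(n);
  for (int j = 0; j < n; ++j) {
    const int k = (j + 1) % n;
    x[j] = poly(j, 0);
    y[j] = poly(j, 1);
    xn[j] = poly(k, 0);
    yn[j] = poly(k, 1);
  }
  const double tol2 = tol * tol;
  LogicalVector out(m);
  for (int i = 0; i < m; ++i) {
    const double px = P(i, 0), py = P(i, 1);
    bool inside = false, boundary = false;
    for (int j = 0; j < n; ++j) {
      const double exj = xn[j] - x[j], eyj = yn[j] - y[j];
      const double len2 = exj * exj + eyj * eyj;
      double tt = len2 > 0 ? ((px - x[j]) * exj + (py - y[j]) * eyj) / len2
                           : 0.0;
      tt = std::min(1.0, std::max(0.0, tt));
      const double ddx = x[j] + tt * exj - px, ddy = y[j] + tt * eyj - py;
      if (ddx * ddx + ddy * ddy <= tol2) {
        boundary = true;
        break;
      }
      if ((y[j] > py) != (yn[j] > py) &&
          px < x[j] + (py - y[j]) * exj / eyj)
        inside = !inside;
    }
    out[i] = boundary || inside;
  }
  return out;
}
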