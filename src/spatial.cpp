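// Spatial kernels shared across the package:
//  - point-in-polygon / point-to-boundary distance (exact, per cell)
//  - scanline polygon rasterization + exact Euclidean distance transform
//    (region band areas on a raster grid)
//  - uniform-grid nearest-neighbour search (proximity metrics)
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Even-odd ray cast for one closed ring (implicitly closed).
static bool point_in_ring(double px, double py, const NumericMatrix& ring) {
  int n = ring.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = ring(i, 0), yi = ring(i, 1);
    double xj = ring(j, 0), yj = ring(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_any(NumericVector px, NumericVector py, List polys) {
  int n = px.size(), np = polys.size();
  LogicalVector out(n, false);
  for (int p = 0; p < np; ++p) {
    NumericMatrix ring = polys[p];
    for (int i = 0; i < n; ++i) {
      if (!out[i] && point_in_ring(px[i], py[i], ring)) out[i] = true;
    }
  }
  return out;
}

static double seg_dist2(double px, double py, double x1, double y1,
                        double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - x1) * dx + (py - y1) * dy) / l2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return qx * qx + qy * qy;
}

// Min distance from each point to any boundary segment of any polygon ring.
// [[Rcpp::export]]
NumericVector cpp_dist_to_boundary(NumericVector px, NumericVector py, List polys) {
  int n = px.size(), np = polys.size();
  NumericVector out(n, INF);
  for (int p = 0; p < np; ++p) {
    NumericMatrix ring = polys[p];
    int m = ring.nrow();
    for (int i = 0; i < n; ++i) {
      double best = out[i] * out[i];
      if (!std::isfinite(best)) best = INF;
      for (int a = 0, b = m - 1; a < m; b = a++) {
        double d2 = seg_dist2(px[i], py[i], ring(b, 0), ring(b, 1),
                              ring(a, 0), ring(a, 1));
        if (d2 < best) best = d2;
      }
      out[i] = std::sqrt(best);
    }
  }
  return out;
}

// Scanline rasterization of the union of simple polygons onto a grid whose
// pixel (row i, col j) has centre (x0 + (j + 0.5) px, y0 + (i + 0.5) px).
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize(List polys, double x0, double y0,
                            int nx, int ny, double px) {
  LogicalMatrix out(ny, nx);
  int np = polys.size();
  std::vector<double> xs;
  for (int p = 0; p < np; ++p) {
    NumericMatrix ring = polys[p];
    int m = ring.nrow();
    for (int i = 0; i < ny; ++i) {
      double yc = y0 + (i + 0.5) * px;
      xs.clear();
      for (int a = 0, b = m - 1; a < m; b = a++) {
        double y1 = ring(b, 1), y2 = ring(a, 1);
        if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
          double x1 = ring(b, 0), x2 = ring(a, 0);
          xs.push_back(x1 + (yc - y1) / (y2 - y1) * (x2 - x1));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        int j0 = (int)std::ceil((xs[k] - x0) / px - 0.5);
        if (j0 < 0) j0 = 0;
        for (int j = j0; j < nx; ++j) {
          double xc = x0 + (j + 0.5) * px;
          if (xc >= xs[k + 1]) break;
          if (xc >= xs[k]) out(i, j) = true;
        }
      }
    }
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher). f is finite;
// "no feature" is encoded as a large finite sentinel so the parabola
// intersections stay well-defined.
static const double DT_LARGE = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in pixel units) from every pixel to the nearest
// TRUE pixel of `feature`. Pixels inside the feature get 0; if the image has
// no TRUE pixel at all, values are >= 1e15 (callers treat that as "no band").
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix feature) {
  int ny = feature.nrow(), nx = feature.ncol();
  NumericMatrix out(ny, nx);
  int nmax = std::max(nx, ny);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) f[i] = feature(i, j) ? 0.0 : DT_LARGE;
    dt1d(f, d, v, z, ny);
    for (int i = 0; i < ny; ++i) out(i, j) = d[i];
  }
  for (int i = 0; i < ny; ++i) {
    for (int j = 0; j < nx; ++j) f[j] = out(i, j);
    dt1d(f, d, v, z, nx);
    for (int j = 0; j < nx; ++j) out(i, j) = d[j];
  }
  return out;
}

struct Grid {
  double x0, y0, h;
  int ncx, ncy;
  std::vector<int> start;   // CSR offsets, ncx*ncy+1
  std::vector<int> idx;     // point indices bucketed by cell
  void build(const NumericVector& x, const NumericVector& y, double cell) {
    int n = x.size();
    double xmin = INF, xmax = -INF, ymin = INF, ymax = -INF;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    h = cell;
    x0 = xmin; y0 = ymin;
    ncx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    ncy = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    std::vector<int> cell_of(n), count(ncx * ncy + 1, 0);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, std::max(0, (int)std::floor((x[i] - x0) / h)));
      int cy = std::min(ncy - 1, std::max(0, (int)std::floor((y[i] - y0) / h)));
      cell_of[i] = cy * ncx + cx;
      ++count[cell_of[i] + 1];
    }
    for (size_t c = 1; c < count.size(); ++c) count[c] += count[c - 1];
    start = count;
    idx.assign(n, 0);
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) idx[cur[cell_of[i]]++] = i;
  }
  void cell_at(double x, double y, int& cx, int& cy) const {
    cx = std::min(ncx - 1, std::max(0, (int)std::floor((x - x0) / h)));
    cy = std::min(ncy - 1, std::max(0, (int)std::floor((y - y0) / h)));
  }
};

// Nearest target for each source point, via expanding ring search on a uniform
// grid. Distances are centroid-to-centroid, or edge-to-edge when surface=TRUE
// (centroid distance minus the two radii, floored at 0). Targets sharing a
// nonzero id with the source (sid/tid) are skipped (self-pair exclusion).
// [[Rcpp::export]]
List cpp_nearest(NumericVector sx, NumericVector sy, NumericVector sr,
                 NumericVector tx, NumericVector ty, NumericVector tr,
                 bool surface, IntegerVector sid, IntegerVector tid) {
  int ns = sx.size(), nt = tx.size();
  NumericVector dist(ns, NA_REAL);
  IntegerVector which(ns, NA_INTEGER);
  if (nt == 0) return List::create(_["distance"] = dist, _["index"] = which);
  bool use_id = (sid.size() == ns) && (tid.size() == nt);
  double maxtr = 0.0;
  for (int j = 0; j < nt; ++j) maxtr = std::max(maxtr, tr[j]);
  // cell size ~ mean spacing, bounded to keep the grid small
  double xspan = (max(tx) - min(tx)), yspan = (max(ty) - min(ty));
  double span = std::max(std::max(xspan, yspan), 1e-9);
  double cell = std::max(span / std::max(1.0, std::floor(std::sqrt((double)nt))), 1e-9);
  Grid g;
  g.build(tx, ty, cell);
  int max_ring = std::max(g.ncx, g.ncy);
  for (int i = 0; i < ns; ++i) {
    int cx, cy;
    g.cell_at(sx[i], sy[i], cx, cy);
    double best = INF;
    int best_j = -1;
    for (int r = 0; r <= max_ring; ++r) {
      double lb = std::max(0, r - 1) * g.h;
      if (surface) lb = std::max(0.0, lb - sr[i] - maxtr);
      if (best_j >= 0 && lb > best) break;
      int xlo = cx - r, xhi = cx + r, ylo = cy - r, yhi = cy + r;
      for (int gy = ylo; gy <= yhi; ++gy) {
        if (gy < 0 || gy >= g.ncy) continue;
        for (int gx = xlo; gx <= xhi; ++gx) {
          if (gx < 0 || gx >= g.ncx) continue;
          // ring only: skip interior cells already visited
          if (r > 0 && gx > xlo && gx < xhi && gy > ylo && gy < yhi) continue;
          int c = gy * g.ncx + gx;
          for (int k = g.start[c]; k < g.start[c + 1]; ++k) {
            int j = g.idx[k];
            if (use_id && sid[i] != 0 && sid[i] == tid[j]) continue;
            double dx = tx[j] - sx[i], dy = ty[j] - sy[i];
            double d = std::sqrt(dx * dx + dy * dy);
            if (surface) d = std::max(0.0, d - sr[i] - tr[j]);
            if (d < best || (d == best && best_j >= 0 && j < best_j)) {
              best = d;
              best_j = j;
            }
          }
        }
      }
    }
    if (best_j >= 0) { dist[i] = best; which[i] = best_j + 1; }
  }
  return List::create(_["distance"] = dist, _["index"] = which);
}

// Number of targets with centroid distance < r (or <= r when inclusive) of
// each source point. Used for local neighbourhood counts.
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericVector sx, NumericVector sy,
                               NumericVector tx, NumericVector ty,
                               double radius, bool inclusive,
                               IntegerVector sid, IntegerVector tid) {
  int ns = sx.size(), nt = tx.size();
  IntegerVector out(ns, 0);
  if (nt == 0 || radius <= 0) return out;
  bool use_id = (sid.size() == ns) && (tid.size() == nt);
  Grid g;
  g.build(tx, ty, radius);
  double r2 = radius * radius;
  for (int i = 0; i < ns; ++i) {
    int cx, cy;
    g.cell_at(sx[i], sy[i], cx, cy);
    int cnt = 0;
    for (int gy = cy - 1; gy <= cy + 1; ++gy) {
      if (gy < 0 || gy >= g.ncy) continue;
      for (int gx = cx - 1; gx <= cx + 1; ++gx) {
        if (gx < 0 || gx >= g.ncx) continue;
        int c = gy * g.ncx + gx;
        for (int k = g.start[c]; k < g.start[c + 1]; ++k) {
          int j = g.idx[k];
          if (use_id && sid[i] != 0 && sid[i] == tid[j]) continue;
          double dx = tx[j] - sx[i], dy = ty[j] - sy[i];
          double d2 = dx * dx + dy * dy;
          if (inclusive ? (d2 <= r2) : (d2 < r2)) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}
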