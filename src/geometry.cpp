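#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- union-find -----------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra] = rb;
}

// Label connected components of a binary image, 8-connectivity.
// img: integer matrix, nonzero = foreground. Returns label matrix
// (0 = background, components numbered 1..K in raster order).
// [[Rcpp::export]]
IntegerMatrix cc_label8(const IntegerMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // column-major storage: idx = r + c*nr
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) continue;
      int i = r + c * nr;
      // link to already-visited neighbours (previous column, and above)
      if (r > 0 && img(r - 1, c)) uf_union(parent, i, i - 1);
      if (c > 0) {
        if (img(r, c - 1)) uf_union(parent, i, i - nr);
        if (r > 0 && img(r - 1, c - 1)) uf_union(parent, i, i - nr - 1);
        if (r + 1 < nr && img(r + 1, c - 1)) uf_union(parent, i, i - nr + 1);
      }
    }
  }

  IntegerMatrix out(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) { out(r, c) = 0; continue; }
      int root = uf_find(parent, r + c * nr);
      if (remap[root] == 0) remap[root] = ++next;
      out(r, c) = remap[root];
    }
  }
  return out;
}

// ---- nearest neighbours ---------------------------------------------------

// k nearest neighbours in X (n x 3) for each query row of Q (m x 3).
// Brute force with partial selection; returns 1-based indices.
// [[Rcpp::export]]
List knn_points(const NumericMatrix& X, const NumericMatrix& Q, int k) {
  const int n = X.nrow(), m = Q.nrow();
  if (k > n) stop("k exceeds number of reference points");
  IntegerMatrix idx(m, k);
  NumericMatrix dst(m, k);
  std::vector<std::pair<double, int> > d(n);
  for (int j = 0; j < m; ++j) {
    const double qx = Q(j, 0), qy = Q(j, 1), qz = Q(j, 2);
    for (int i = 0; i < n; ++i) {
      const double dx = X(i, 0) - qx, dy = X(i, 1) - qy, dz = X(i, 2) - qz;
      d[i] = std::make_pair(dx * dx + dy * dy + dz * dz, i);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int t = 0; t < k; ++t) {
      idx(j, t) = d[t].second + 1;
      dst(j, t) = std::sqrt(d[t].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Single nearest neighbour in X for each row of Q.
// [[Rcpp::export]]
List nn1_points(const NumericMatrix& X, const NumericMatrix& Q) {
  const int n = X.nrow(), m = Q.nrow();
  if (n < 1) stop("empty reference set");
  IntegerVector idx(m);
  NumericVector dst(m);
  for (int j = 0; j < m; ++j) {
    const double qx = Q(j, 0), qy = Q(j, 1), qz = Q(j, 2);
    double best = R_PosInf; int bi = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = X(i, 0) - qx, dy = X(i, 1) - qy, dz = X(i, 2) - qz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bi = i; }
    }
    idx[j] = bi + 1;
    dst[j] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Single-linkage clustering at linkage distance eps: connected components
// of the eps-neighbourhood graph. Returns 1-based component labels.
// [[Rcpp::export]]
IntegerVector cluster_eps_cpp(const NumericMatrix& X, double eps) {
  const int n = X.nrow();
  const double e2 = eps * eps;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  // sort by x to restrict the pair scan
  std::vector<std::pair<double, int> > ord(n);
  for (int i = 0; i < n; ++i) ord[i] = std::make_pair(X(i, 0), i);
  std::sort(ord.begin(), ord.end());
  for (int a = 0; a < n; ++a) {
    const int i = ord[a].second;
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    for (int b = a + 1; b < n; ++b) {
      if (ord[b].first - ord[a].first > eps) break;
      const int j = ord[b].second;
      const double dx = X(j, 0) - xi, dy = X(j, 1) - yi, dz = X(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz <= e2) uf_union(parent, i, j);
    }
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int root = uf_find(parent, i);
    if (remap[root] == 0) remap[root] = ++next;
    lab[i] = remap[root];
  }
  return lab;
}

// ---- ray casting ----------------------------------------------------------

// Surface encodings (one row per surface, last column = integer id):
//   spheres: cx cy cz r id                                  (5 cols)
//   rects:   cx cy cz ux uy uz vx vy vz hu hv id            (12 cols)
//            u,v unit in-plane axes, hu,hv half extents
//   cyls:    px py pz ax ay az len r id                     (9 cols)
//            p = base point, a unit axis, lateral surface for s in [0,len]
//   disks:   cx cy cz nx ny nz r id                         (8 cols)
// Rays: origins (m x 3), dirs (m x 3, unit not required).
// Returns nearest positive hit parameter t (NA when no hit) and surface id.
// When a ray direction has zero travel-axis (y) component, surfaces whose
// y-interval excludes the ray's y are skipped cheaply.
// [[Rcpp::export]]
List raycast_cpp(const NumericMatrix& origins, const NumericMatrix& dirs,
                 const NumericMatrix& spheres, const NumericMatrix& rects,
                 const NumericMatrix& cyls, const NumericMatrix& disks,
                 double t_min = 1e-9) {
  const int m = origins.nrow();
  const int ns = spheres.nrow(), nr = rects.nrow(), ncy = cyls.nrow(),
            nd = disks.nrow();
  NumericVector tt(m, NA_REAL);
  IntegerVector id(m, NA_INTEGER);

  // y-intervals for the slab reject
  std::vector<double> sy0(ns), sy1(ns), ry0(nr), ry1(nr), cy0(ncy), cy1(ncy),
      dy0(nd), dy1(nd);
  for (int i = 0; i < ns; ++i) {
    sy0[i] = spheres(i, 1) - spheres(i, 3);
    sy1[i] = spheres(i, 1) + spheres(i, 3);
  }
  for (int i = 0; i < nr; ++i) {
    const double ey = std::fabs(rects(i, 4)) * rects(i, 9) +
                      std::fabs(rects(i, 7)) * rects(i, 10);
    ry0[i] = rects(i, 1) - ey;
    ry1[i] = rects(i, 1) + ey;
  }
  for (int i = 0; i < ncy; ++i) {
    const double a = cyls(i, 4) * cyls(i, 6);
    cy0[i] = std::min(cyls(i, 1), cyls(i, 1) + a) - cyls(i, 7);
    cy1[i] = std::max(cyls(i, 1), cyls(i, 1) + a) + cyls(i, 7);
  }
  for (int i = 0; i < nd; ++i) {
    dy0[i] = disks(i, 1) - disks(i, 6);
    dy1[i] = disks(i, 1) + disks(i, 6);
  }

  for (int q = 0; q < m; ++q) {
    const double ox = origins(q, 0), oy = origins(q, 1), oz = origins(q, 2);
    const double dx = dirs(q, 0), dy = dirs(q, 1), dz = dirs(q, 2);
    const bool planar = (dy == 0.0);
    double best = R_PosInf;
    int bestid = NA_INTEGER;

    for (int i = 0; i < ns; ++i) {
      if (planar && (oy < sy0[i] || oy > sy1[i])) continue;
      const double ex = ox - spheres(i, 0), ey = oy - spheres(i, 1),
                   ez = oz - spheres(i, 2);
      const double A = dx * dx + dy * dy + dz * dz;
      const double B = 2.0 * (ex * dx + ey * dy + ez * dz);
      const double C = ex * ex + ey * ey + ez * ez -
                       spheres(i, 3) * spheres(i, 3);
      const double disc = B * B - 4.0 * A * C;
      if (disc < 0) continue;
      const double sq = std::sqrt(disc);
      double t = (-B - sq) / (2.0 * A);
      if (t < t_min) t = (-B + sq) / (2.0 * A);
      if (t >= t_min && t < best) { best = t; bestid = (int)spheres(i, 4); }
    }

    for (int i = 0; i < nr; ++i) {
      if (planar && (oy < ry0[i] || oy > ry1[i])) continue;
      const double ux = rects(i, 3), uy = rects(i, 4), uz = rects(i, 5);
      const double vx = rects(i, 6), vy = rects(i, 7), vz = rects(i, 8);
      const double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
                   nz = ux * vy - uy * vx;
      const double dn = dx * nx + dy * ny + dz * nz;
      if (std::fabs(dn) < 1e-15) continue;
      const double wx = rects(i, 0) - ox, wy = rects(i, 1) - oy,
                   wz = rects(i, 2) - oz;
      const double t = (wx * nx + wy * ny + wz * nz) / dn;
      if (t < t_min || t >= best) continue;
      const double px = ox + t * dx - rects(i, 0),
                   py = oy + t * dy - rects(i, 1),
                   pz = oz + t * dz - rects(i, 2);
      const double su = px * ux + py * uy + pz * uz;
      const double sv = px * vx + py * vy + pz * vz;
      if (std::fabs(su) <= rects(i, 9) && std::fabs(sv) <= rects(i, 10)) {
        best = t; bestid = (int)rects(i, 11);
      }
    }

    for (int i = 0; i < ncy; ++i) {
      if (planar && (oy < cy0[i] || oy > cy1[i])) continue;
      const double ax = cyls(i, 3), ay = cyls(i, 4), az = cyls(i, 5);
      const double ex = ox - cyls(i, 0), ey = oy - cyls(i, 1),
                   ez = oz - cyls(i, 2);
      const double da = dx * ax + dy * ay + dz * az;
      const double ea = ex * ax + ey * ay + ez * az;
      const double fx = dx - da * ax, fy = dy - da * ay, fz = dz - da * az;
      const double gx = ex - ea * ax, gy = ey - ea * ay, gz = ez - ea * az;
      const double A = fx * fx + fy * fy + fz * fz;
      if (A < 1e-18) continue; // ray parallel to axis
      const double B = 2.0 * (fx * gx + fy * gy + fz * gz);
      const double C = gx * gx + gy * gy + gz * gz - cyls(i, 7) * cyls(i, 7);
      const double disc = B * B - 4.0 * A * C;
      if (disc < 0) continue;
      const double sq = std::sqrt(disc);
      for (int s = 0; s < 2; ++s) {
        const double t = (s == 0) ? (-B - sq) / (2.0 * A)
                                  : (-B + sq) / (2.0 * A);
        if (t < t_min || t >= best) continue;
        const double h = ea + t * da; // axial coordinate of the hit
        if (h >= 0.0 && h <= cyls(i, 6)) {
          best = t; bestid = (int)cyls(i, 8);
          break;
        }
      }
    }

    for (int i = 0; i < nd; ++i) {
      if (planar && (oy < dy0[i] || oy > dy1[i])) continue;
      const double nx = disks(i, 3), ny = disks(i, 4), nz = disks(i, 5);
      const double dn = dx * nx + dy * ny + dz * nz;
      if (std::fabs(dn) < 1e-15) continue;
      const double wx = disks(i, 0) - ox, wy = disks(i, 1) - oy,
                   wz = disks(i, 2) - oz;
      const double t = (wx * nx + wy * ny + wz * nz) / dn;
      if (t < t_min || t >= best) continue;
      const double px = ox + t * dx - disks(i, 0),
                   py = oy + t * dy - disks(i, 1),
                   pz = oz + t * dz - disks(i, 2);
      if (px * px + py * py + pz * pz <= disks(i, 6) * disks(i, 6)) {
        best = t; bestid = (int)disks(i, 7);
      }
    }

    if (R_finite(best)) { tt[q] = best; id[q] = bestid; }
  }
  return List::create(_["t"] = tt, _["id"] = id);
}
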