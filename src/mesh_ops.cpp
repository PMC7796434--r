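#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Geometry kernels for triangle meshes: ray-parity interior tests and
// closest-point-on-surface queries. Vertices are an n x 3 matrix (mm),
// faces an m x 3 integer matrix of 0-based vertex indices.

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Moller-Trumbore ray/triangle intersection. Returns t >= 0 on hit, -1 miss.
// 'degenerate' is set when the hit grazes an edge/vertex or the triangle is
// near-parallel to the ray, in which case the parity count is unreliable.
static double ray_tri(const double* orig, const double* dir,
                      const double* v0, const double* v1, const double* v2,
                      bool& degenerate) {
  const double eps = 1e-12;
  double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
  for (int i = 0; i < 3; ++i) { e1[i] = v1[i] - v0[i]; e2[i] = v2[i] - v0[i]; }
  pvec[0] = dir[1] * e2[2] - dir[2] * e2[1];
  pvec[1] = dir[2] * e2[0] - dir[0] * e2[2];
  pvec[2] = dir[0] * e2[1] - dir[1] * e2[0];
  double det = dot3(e1, pvec);
  double scale = std::sqrt(dot3(e1, e1)) * std::sqrt(dot3(e2, e2));
  if (std::fabs(det) < eps * std::max(scale, 1.0)) { degenerate = false; return -1.0; }
  double inv_det = 1.0 / det;
  for (int i = 0; i < 3; ++i) tvec[i] = orig[i] - v0[i];
  double u = dot3(tvec, pvec) * inv_det;
  qvec[0] = tvec[1] * e1[2] - tvec[2] * e1[1];
  qvec[1] = tvec[2] * e1[0] - tvec[0] * e1[2];
  qvec[2] = tvec[0] * e1[1] - tvec[1] * e1[0];
  double v = dot3(dir, qvec) * inv_det;
  const double beps = 1e-9;
  if (u < -beps || v < -beps || u + v > 1.0 + beps) { degenerate = false; return -1.0; }
  double t = dot3(e2, qvec) * inv_det;
  if (t <= 0) { degenerate = false; return -1.0; }
  degenerate = (u < beps || v < beps || u + v > 1.0 - beps);
  return t;
}

// [[Rcpp::export(name = ".cpp_points_in_mesh")]]
LogicalVector cpp_points_in_mesh(NumericMatrix points, NumericMatrix vertices,
                                 IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  LogicalVector inside(np);
  // first attempt casts along +z, allowing a cheap x/y bounding-box reject
  // per triangle; grazing hits fall back to generic ray directions
  const double zdir[3] = {0.0, 0.0, 1.0};
  const double dirs[5][3] = {
    {0.5377396, 0.3190127, 0.7804431},
    {-0.2316772, 0.8914262, 0.3895443},
    {0.7071843, -0.5223991, 0.4763712},
    {-0.4462117, -0.3119215, -0.8388312},
    {0.1093717, 0.6480321, -0.7537149}};
  std::vector<double> V(vertices.nrow() * 3);
  for (int i = 0; i < vertices.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = vertices(i, j);
  std::vector<double> bxmin(nf), bxmax(nf), bymin(nf), bymax(nf), bzmax(nf);
  for (int f = 0; f < nf; ++f) {
    const double* a = &V[3 * faces(f, 0)];
    const double* b = &V[3 * faces(f, 1)];
    const double* c = &V[3 * faces(f, 2)];
    bxmin[f] = std::min(a[0], std::min(b[0], c[0]));
    bxmax[f] = std::max(a[0], std::max(b[0], c[0]));
    bymin[f] = std::min(a[1], std::min(b[1], c[1]));
    bymax[f] = std::max(a[1], std::max(b[1], c[1]));
    bzmax[f] = std::max(a[2], std::max(b[2], c[2]));
  }
  for (int p = 0; p < np; ++p) {
    double orig[3] = {points(p, 0), points(p, 1), points(p, 2)};
    bool done = false;
    {
      int crossings = 0;
      bool bad = false;
      for (int f = 0; f < nf; ++f) {
        if (orig[0] < bxmin[f] || orig[0] > bxmax[f] ||
            orig[1] < bymin[f] || orig[1] > bymax[f] || orig[2] > bzmax[f])
          continue;
        bool degen;
        double t = ray_tri(orig, zdir, &V[3 * faces(f, 0)],
                           &V[3 * faces(f, 1)], &V[3 * faces(f, 2)], degen);
        if (t > 0) {
          if (degen) { bad = true; break; }
          ++crossings;
        }
      }
      if (!bad) { inside[p] = (crossings % 2) == 1; done = true; }
    }
    for (int d = 0; d < 5 && !done; ++d) {
      int crossings = 0;
      bool bad = false;
      for (int f = 0; f < nf && !bad; ++f) {
        bool degen;
        double t = ray_tri(orig, dirs[d], &V[3 * faces(f, 0)],
                           &V[3 * faces(f, 1)], &V[3 * faces(f, 2)], degen);
        if (t > 0) {
          if (degen) { bad = true; break; }
          ++crossings;
        }
      }
      if (!bad) { inside[p] = (crossings % 2) == 1; done = true; }
    }
    if (!done) inside[p] = false; // all rays grazed; treat as boundary/outside
  }
  return inside;
}

// closest point on a single triangle (Ericson, Real-Time Collision Detection)
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export(name = ".cpp_closest_point_on_mesh")]]
List cpp_closest_point_on_mesh(NumericMatrix points, NumericMatrix vertices,
                               IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  NumericMatrix closest(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  std::vector<double> V(vertices.nrow() * 3);
  for (int i = 0; i < vertices.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = vertices(i, j);
  // per-triangle centroid and circumscribing radius for cheap lower bounds
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    const double* a = &V[3 * faces(f, 0)];
    const double* b = &V[3 * faces(f, 1)];
    const double* c = &V[3 * faces(f, 2)];
    cx[f] = (a[0] + b[0] + c[0]) / 3.0;
    cy[f] = (a[1] + b[1] + c[1]) / 3.0;
    cz[f] = (a[2] + b[2] + c[2]) / 3.0;
    double r2 = 0;
    for (int k = 0; k < 3; ++k) {
      const double* v = &V[3 * faces(f, k)];
      double dx = v[0] - cx[f], dy = v[1] - cy[f], dz = v[2] - cz[f];
      r2 = std::max(r2, dx * dx + dy * dy + dz * dz);
    }
    rad[f] = std::sqrt(r2);
  }
  for (int p = 0; p < np; ++p) {
    double pt[3] = {points(p, 0), points(p, 1), points(p, 2)};
    double best = R_PosInf;
    int bestf = -1;
    double bestpt[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      double dx = pt[0] - cx[f], dy = pt[1] - cy[f], dz = pt[2] - cz[f];
      double lb = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[f];
      if (lb * lb >= best && lb > 0) continue;
      double q[3];
      closest_on_tri(pt, &V[3 * faces(f, 0)], &V[3 * faces(f, 1)],
                     &V[3 * faces(f, 2)], q);
      double ddx = pt[0] - q[0], ddy = pt[1] - q[1], ddz = pt[2] - q[2];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best) {
        best = d2;
        bestf = f;
        bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
      }
    }
    closest(p, 0) = bestpt[0]; closest(p, 1) = bestpt[1]; closest(p, 2) = bestpt[2];
    dist[p] = std::sqrt(best);
    face[p] = bestf + 1; // 1-based for R
  }
  return List::create(_["points"] = closest, _["distance"] = dist,
                      _["face"] = face);
}
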