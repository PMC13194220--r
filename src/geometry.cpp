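#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Geometric kernels shared by the mesh primitives.  All inputs are plain
// matrices: points are n x 3, faces are 0-based m x 3 index triples.

// [[Rcpp::export]]
NumericVector cpp_nearest_dist(const NumericMatrix& pts,
                               const NumericMatrix& targets) {
  const int n = pts.nrow(), m = targets.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = px - targets(j, 0);
      const double dy = py - targets(j, 1);
      const double dz = pz - targets(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_nearest_index(const NumericMatrix& pts,
                                const NumericMatrix& targets) {
  const int n = pts.nrow(), m = targets.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - targets(j, 0);
      const double dy = py - targets(j, 1);
      const double dz = pz - targets(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = j; }
    }
    out[i] = arg + 1;  // 1-based for R
  }
  return out;
}

// Generalized winding number: sum of signed solid angles subtended by each
// face (Van Oosterom & Strackee), divided by 4*pi.  ~1 inside a closed
// outward-oriented surface, ~0 outside.
// [[Rcpp::export]]
NumericVector cpp_winding_number(const NumericMatrix& pts,
                                 const NumericMatrix& V,
                                 const IntegerMatrix& F) {
  const int n = pts.nrow(), m = F.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double omega = 0.0;
    for (int f = 0; f < m; ++f) {
      const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      const double ax = V(ia, 0) - px, ay = V(ia, 1) - py, az = V(ia, 2) - pz;
      const double bx = V(ib, 0) - px, by = V(ib, 1) - py, bz = V(ib, 2) - pz;
      const double cx = V(ic, 0) - px, cy = V(ic, 1) - py, cz = V(ic, 2) - pz;
      const double la = std::sqrt(ax * ax + ay * ay + az * az);
      const double lb = std::sqrt(bx * bx + by * by + bz * bz);
      const double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
      // det[a b c]
      const double det = ax * (by * cz - bz * cy)
                       - ay * (bx * cz - bz * cx)
                       + az * (bx * cy - by * cx);
      const double den = la * lb * lc
                       + (ax * bx + ay * by + az * bz) * lc
                       + (bx * cx + by * cy + bz * cz) * la
                       + (cx * ax + cy * ay + cz * az) * lb;
      omega += 2.0 * std::atan2(det, den);
    }
    out[i] = omega / (4.0 * M_PI);
  }
  return out;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Squared distance from point p to triangle (a, b, c); Ericson's
// closest-point-on-triangle construction via barycentric region tests.
static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double qx, qy, qz;
  if (d1 <= 0.0 && d2 <= 0.0) {
    qx = a[0]; qy = a[1]; qz = a[2];
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) {
      bp[k] = p[k] - b[k];
      cp[k] = p[k] - c[k];
    }
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      qx = b[0]; qy = b[1]; qz = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      qx = c[0]; qy = c[1]; qz = c[2];
    } else {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        const double t = clamp01(d1 / (d1 - d3));
        qx = a[0] + t * ab[0]; qy = a[1] + t * ab[1]; qz = a[2] + t * ab[2];
      } else {
        const double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          const double t = clamp01(d2 / (d2 - d6));
          qx = a[0] + t * ac[0]; qy = a[1] + t * ac[1]; qz = a[2] + t * ac[2];
        } else {
          const double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            const double t = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));
            qx = b[0] + t * (c[0] - b[0]);
            qy = b[1] + t * (c[1] - b[1]);
            qz = b[2] + t * (c[2] - b[2]);
          } else {
            const double denom = 1.0 / (va + vb + vc);
            const double v = vb * denom, w = vc * denom;
            qx = a[0] + ab[0] * v + ac[0] * w;
            qy = a[1] + ab[1] * v + ac[1] * w;
            qz = a[2] + ab[2] * v + ac[2] * w;
          }
        }
      }
    }
  }
  const double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_surface_dist(const NumericMatrix& pts,
                                     const NumericMatrix& V,
                                     const IntegerMatrix& F) {
  const int n = pts.nrow(), m = F.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double best = R_PosInf;
    for (int f = 0; f < m; ++f) {
      const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3] = { V(ia, 0), V(ia, 1), V(ia, 2) };
      double b[3] = { V(ib, 0), V(ib, 1), V(ib, 2) };
      double c[3] = { V(ic, 0), V(ic, 1), V(ic, 2) };
      const double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Ray-triangle crossing parity (Moller-Trumbore) per point per direction;
// fallback containment test for non-watertight meshes.
// [[Rcpp::export]]
IntegerMatrix cpp_ray_parity(const NumericMatrix& pts,
                             const NumericMatrix& V,
                             const IntegerMatrix& F,
                             const NumericMatrix& dirs) {
  const int n = pts.nrow(), m = F.nrow(), nd = dirs.nrow();
  IntegerMatrix out(n, nd);
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) {
    const double ox = pts(i, 0), oy = pts(i, 1), oz = pts(i, 2);
    for (int d = 0; d < nd; ++d) {
      const double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
      int hits = 0;
      for (int f = 0; f < m; ++f) {
        const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
        const double e1x = V(ib, 0) - V(ia, 0);
        const double e1y = V(ib, 1) - V(ia, 1);
        const double e1z = V(ib, 2) - V(ia, 2);
        const double e2x = V(ic, 0) - V(ia, 0);
        const double e2y = V(ic, 1) - V(ia, 1);
        const double e2z = V(ic, 2) - V(ia, 2);
        const double hx = dy * e2z - dz * e2y;
        const double hy = dz * e2x - dx * e2z;
        const double hz = dx * e2y - dy * e2x;
        const double det = e1x * hx + e1y * hy + e1z * hz;
        if (std::fabs(det) < eps) continue;
        const double inv = 1.0 / det;
        const double sx = ox - V(ia, 0);
        const double sy = oy - V(ia, 1);
        const double sz = oz - V(ia, 2);
        const double u = inv * (sx * hx + sy * hy + sz * hz);
        if (u < 0.0 || u > 1.0) continue;
        const double qx = sy * e1z - sz * e1y;
        const double qy = sz * e1x - sx * e1z;
        const double qz = sx * e1y - sy * e1x;
        const double v = inv * (dx * qx + dy * qy + dz * qz);
        if (v < 0.0 || u + v > 1.0) continue;
        const double t = inv * (e2x * qx + e2y * qy + e2z * qz);
        if (t > eps) ++hits;
      }
      out(i, d) = hits % 2;
    }
  }
  return out;
}

// Angle-weighted vertex pseudo-normals (Baerentzen & Aanaes); used to sign
// nearest-vertex distances cheaply inside the optimizer's smooth objective.
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(const NumericMatrix& V,
                                 const IntegerMatrix& F) {
  const int nv = V.nrow(), m = F.nrow();
  NumericMatrix N(nv, 3);
  for (int f = 0; f < m; ++f) {
    const int id[3] = { F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1 };
    double e[3][3];
    for (int k = 0; k < 3; ++k) {
      const int a = id[k], b = id[(k + 1) % 3];
      e[k][0] = V(b, 0) - V(a, 0);
      e[k][1] = V(b, 1) - V(a, 1);
      e[k][2] = V(b, 2) - V(a, 2);
    }
    // face normal
    const double nx = e[0][1] * e[1][2] - e[0][2] * e[1][1];
    const double ny = e[0][2] * e[1][0] - e[0][0] * e[1][2];
    const double nz = e[0][0] * e[1][1] - e[0][1] * e[1][0];
    const double nl = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nl < 1e-30) continue;
    for (int k = 0; k < 3; ++k) {
      // angle at vertex id[k] between edges k and (k+2 reversed)
      const double* u = e[k];
      double w[3] = { -e[(k + 2) % 3][0], -e[(k + 2) % 3][1],
                      -e[(k + 2) % 3][2] };
      const double lu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
      const double lw = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
      if (lu < 1e-30 || lw < 1e-30) continue;
      double cosa = (u[0]*w[0] + u[1]*w[1] + u[2]*w[2]) / (lu * lw);
      cosa = cosa > 1.0 ? 1.0 : (cosa < -1.0 ? -1.0 : cosa);
      const double ang = std::acos(cosa);
      N(id[k], 0) += ang * nx / nl;
      N(id[k], 1) += ang * ny / nl;
      N(id[k], 2) += ang * nz / nl;
    }
  }
  for (int i = 0; i < nv; ++i) {
    const double l = std::sqrt(N(i,0)*N(i,0) + N(i,1)*N(i,1) + N(i,2)*N(i,2));
    if (l > 1e-30) { N(i,0) /= l; N(i,1) /= l; N(i,2) /= l; }
  }
  return N;
}

// Distance to the nearest target vertex, negated when the query point lies
// behind that vertex's pseudo-normal (approximately inside the surface).
// [[Rcpp::export]]
NumericVector cpp_nearest_signed(const NumericMatrix& pts,
                                 const NumericMatrix& V,
                                 const NumericMatrix& VN) {
  const int n = pts.nrow(), m = V.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - V(j, 0);
      const double dy = py - V(j, 1);
      const double dz = pz - V(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = j; }
    }
    const double d = std::sqrt(best);
    const double dot = (px - V(arg, 0)) * VN(arg, 0)
                     + (py - V(arg, 1)) * VN(arg, 1)
                     + (pz - V(arg, 2)) * VN(arg, 2);
    out[i] = dot >= 0.0 ? d : -d;
  }
  return out;
}
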