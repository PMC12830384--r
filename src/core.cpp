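#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- small vector helpers -------------------------------------------------

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// min squared distance from one point to every row of B
static double min_sqdist(const double p[3], const NumericMatrix &B) {
  double best = R_PosInf;
  const int m = B.nrow();
  for (int j = 0; j < m; ++j) {
    double dx = p[0] - B(j, 0), dy = p[1] - B(j, 1), dz = p[2] - B(j, 2);
    double d = dx * dx + dy * dy + dz * dz;
    if (d < best) best = d;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {A(i, 0), A(i, 1), A(i, 2)};
    out[i] = std::sqrt(min_sqdist(p, B));
  }
  return out;
}

// Symmetric Chamfer distance: mean nearest-neighbour distance A->B plus
// mean nearest-neighbour distance B->A (sum of the two means, no 1/2).
// [[Rcpp::export]]
double cpp_chamfer(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  double sa = 0.0, sb = 0.0;
  for (int i = 0; i < n; ++i) {
    double p[3] = {A(i, 0), A(i, 1), A(i, 2)};
    sa += std::sqrt(min_sqdist(p, B));
  }
  for (int j = 0; j < m; ++j) {
    double p[3] = {B(j, 0), B(j, 1), B(j, 2)};
    sb += std::sqrt(min_sqdist(p, A));
  }
  return sa / n + sb / m;
}

// Chamfer between points and the template placed as c + r * uv, factored
// through cached inner products so that, for a fixed center, all radius
// scalings reuse one O(N*M) pass:
//   |p_i - c - r u_j|^2 = A_i + r^2 U_j - 2 r B_ij,
// with A_i = |p_i - c|^2, U_j = |u_j|^2, B_ij = (p_i - c) . u_j.
struct SphereChamferCache {
  int n, m;
  std::vector<double> A, B, Bmax, U;
  bool unit;  // all template vertices unit-norm (true sphere template)

  void build(const NumericMatrix &pts, const NumericMatrix &uv,
             const double c[3]) {
    n = pts.nrow();
    m = uv.nrow();
    A.resize(n);
    B.resize((size_t)n * m);
    Bmax.resize(n);
    if ((int)U.size() != m) {
      U.resize(m);
      unit = true;
      for (int j = 0; j < m; ++j) {
        U[j] = uv(j, 0) * uv(j, 0) + uv(j, 1) * uv(j, 1) + uv(j, 2) * uv(j, 2);
        if (std::fabs(U[j] - 1.0) > 1e-12) unit = false;
      }
    }
    for (int i = 0; i < n; ++i) {
      double wx = pts(i, 0) - c[0], wy = pts(i, 1) - c[1],
             wz = pts(i, 2) - c[2];
      A[i] = wx * wx + wy * wy + wz * wz;
      double bmax = -R_PosInf;
      double *row = &B[(size_t)i * m];
      for (int j = 0; j < m; ++j) {
        double b = wx * uv(j, 0) + wy * uv(j, 1) + wz * uv(j, 2);
        row[j] = b;
        if (b > bmax) bmax = b;
      }
      Bmax[i] = bmax;
    }
  }

  double eval(double r) const {
    double r2 = r * r;
    double sa = 0.0;
    if (unit) {
      for (int i = 0; i < n; ++i) {
        double d = A[i] + r2 - 2.0 * r * Bmax[i];
        sa += std::sqrt(d > 0 ? d : 0);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double *row = &B[(size_t)i * m];
        double best = R_PosInf;
        for (int j = 0; j < m; ++j) {
          double d = r2 * U[j] - 2.0 * r * row[j];
          if (d < best) best = d;
        }
        double d = A[i] + best;
        sa += std::sqrt(d > 0 ? d : 0);
      }
    }
    double sb = 0.0;
    for (int j = 0; j < m; ++j) {
      double best = R_PosInf;
      const double *col = &B[j];
      for (int i = 0; i < n; ++i) {
        double d = A[i] - 2.0 * r * col[(size_t)i * m];
        if (d < best) best = d;
      }
      double d = best + r2 * U[j];
      sb += std::sqrt(d > 0 ? d : 0);
    }
    return sa / n + sb / m;
  }
};

// chamfer between points and a sphere mesh placed as c + r * unit_verts,
// without materialising the transformed vertex matrix
static double chamfer_sphere(const NumericMatrix &pts, const NumericMatrix &uv,
                             const double c[3], double r) {
  const int n = pts.nrow(), m = uv.nrow();
  double sa = 0.0;
  std::vector<double> vmin(m, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = px - (c[0] + r * uv(j, 0));
      double dy = py - (c[1] + r * uv(j, 1));
      double dz = pz - (c[2] + r * uv(j, 2));
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
      if (d < vmin[j]) vmin[j] = d;
    }
    sa += std::sqrt(best);
  }
  double sb = 0.0;
  for (int j = 0; j < m; ++j) sb += std::sqrt(vmin[j]);
  return sa / n + sb / m;
}

// Greedy local refinement of a sphere hypothesis.  Each iteration scores the
// 35 candidates given by {no move, +/-step on x, y, z} x the radius grid
// scales * r0 (the scalings multiply the user-set initial radius, so the
// reachable radii stay anchored to that physical prior) and adopts the
// strict minimiser; stops when the Chamfer score drops below d_th1, the
// improvement drops below d_th2, or n_refi iterations elapse.
// [[Rcpp::export]]
List cpp_refine_sphere(NumericMatrix pts, NumericMatrix unit_verts,
                       NumericVector c0, double r0, double step,
                       NumericVector scales, double d_th1, double d_th2,
                       int n_refi) {
  double c[3] = {c0[0], c0[1], c0[2]};
  double r = r0;
  const int ns = scales.size();
  static const double tdir[7][3] = {
      {0, 0, 0}, {1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
      {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};

  double cur = chamfer_sphere(pts, unit_verts, c, r);
  std::vector<double> trace;
  trace.push_back(cur);
  SphereChamferCache cache;
  int it = 0;
  while (it < n_refi) {
    ++it;
    double best = cur;
    int bt = -1, bs = -1;
    for (int t = 0; t < 7; ++t) {
      double cc[3] = {c[0] + step * tdir[t][0], c[1] + step * tdir[t][1],
                      c[2] + step * tdir[t][2]};
      cache.build(pts, unit_verts, cc);
      for (int s = 0; s < ns; ++s) {
        double rc = r0 * scales[s];
        if (t == 0 && rc == r) continue;  // identity = current state
        double ch = cache.eval(rc);
        if (ch < best) { best = ch; bt = t; bs = s; }
      }
    }
    double improvement = cur - best;
    if (bt >= 0) {
      c[0] += step * tdir[bt][0];
      c[1] += step * tdir[bt][1];
      c[2] += step * tdir[bt][2];
      r = r0 * scales[bs];
      cur = best;
    }
    trace.push_back(cur);
    if (cur < d_th1 || improvement < d_th2) break;
  }
  return List::create(_["center"] = NumericVector::create(c[0], c[1], c[2]),
                      _["radius"] = r, _["chamfer"] = cur,
                      _["iterations"] = it, _["trace"] = wrap(trace));
}

static double chamfer_placed(const NumericMatrix &pts, const NumericMatrix &uv,
                             const double c[3], const double s[3],
                             const double R[9]) {
  const int n = pts.nrow(), m = uv.nrow();
  std::vector<double> vx(m), vy(m), vz(m);
  for (int j = 0; j < m; ++j) {
    double x = s[0] * uv(j, 0), y = s[1] * uv(j, 1), z = s[2] * uv(j, 2);
    vx[j] = R[0] * x + R[1] * y + R[2] * z + c[0];
    vy[j] = R[3] * x + R[4] * y + R[5] * z + c[1];
    vz[j] = R[6] * x + R[7] * y + R[8] * z + c[2];
  }
  double sa = 0.0;
  std::vector<double> vmin(m, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = px - vx[j], dy = py - vy[j], dz = pz - vz[j];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
      if (d < vmin[j]) vmin[j] = d;
    }
    sa += std::sqrt(best);
  }
  double sb = 0.0;
  for (int j = 0; j < m; ++j) sb += std::sqrt(vmin[j]);
  return sa / n + sb / m;
}

// re-orthonormalise a rotation matrix in place (modified Gram-Schmidt)
static void orthonormalise(double R[9]) {
  double c0[3] = {R[0], R[3], R[6]};
  double c1[3] = {R[1], R[4], R[7]};
  double n0 = std::sqrt(dot3(c0, c0));
  for (int i = 0; i < 3; ++i) c0[i] /= n0;
  double p = dot3(c0, c1);
  for (int i = 0; i < 3; ++i) c1[i] -= p * c0[i];
  double n1 = std::sqrt(dot3(c1, c1));
  for (int i = 0; i < 3; ++i) c1[i] /= n1;
  double c2[3];
  cross3(c0, c1, c2);
  R[0] = c0[0]; R[3] = c0[1]; R[6] = c0[2];
  R[1] = c1[0]; R[4] = c1[1]; R[7] = c1[2];
  R[2] = c2[0]; R[5] = c2[1]; R[8] = c2[2];
}

static void axis_rot(int axis, double deg, double M[9]) {
  double a = deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  for (int i = 0; i < 9; ++i) M[i] = 0.0;
  if (axis == 0) {
    M[0] = 1; M[4] = ca; M[5] = -sa; M[7] = sa; M[8] = ca;
  } else if (axis == 1) {
    M[0] = ca; M[2] = sa; M[4] = 1; M[6] = -sa; M[8] = ca;
  } else {
    M[0] = ca; M[1] = -sa; M[3] = sa; M[4] = ca; M[8] = 1;
  }
}

static void matmul3(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * i + k] * B[3 * k + j];
      C[3 * i + j] = s;
    }
}

// Detailed fit: greedy coordinate descent over single moves -- translations
// (+/-step per axis), per-axis scale factors, and +/-rot_deg rotations about
// the world axes -- with the same three stopping criteria as the sphere
// refinement.  Scales are clamped to [smin, smax].
// [[Rcpp::export]]
List cpp_detailed_fit(NumericMatrix pts, NumericMatrix unit_verts,
                      NumericVector c0, NumericVector s0, NumericMatrix R0,
                      double step, NumericVector scale_factors, double rot_deg,
                      double d_th1, double d_th2, int n_refi, double smin,
                      double smax) {
  double c[3] = {c0[0], c0[1], c0[2]};
  double s[3] = {s0[0], s0[1], s0[2]};
  double R[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = R0(i, j);

  const int nf = scale_factors.size();
  static const double tdir[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                                    {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
  double cur = chamfer_placed(pts, unit_verts, c, s, R);
  std::vector<double> trace;
  trace.push_back(cur);
  int it = 0;
  while (it < n_refi) {
    ++it;
    double best = cur;
    int kind = -1, a1 = 0, a2 = 0;  // kind 0: translate, 1: scale, 2: rotate
    // translations
    for (int t = 0; t < 6; ++t) {
      double cc[3] = {c[0] + step * tdir[t][0], c[1] + step * tdir[t][1],
                      c[2] + step * tdir[t][2]};
      double ch = chamfer_placed(pts, unit_verts, cc, s, R);
      if (ch < best) { best = ch; kind = 0; a1 = t; }
    }
    // per-axis scalings
    for (int ax = 0; ax < 3; ++ax) {
      for (int f = 0; f < nf; ++f) {
        if (scale_factors[f] == 1.0) continue;
        double ns_ = s[ax] * scale_factors[f];
        if (ns_ < smin) ns_ = smin;
        if (ns_ > smax) ns_ = smax;
        if (ns_ == s[ax]) continue;
        double ss[3] = {s[0], s[1], s[2]};
        ss[ax] = ns_;
        double ch = chamfer_placed(pts, unit_verts, c, ss, R);
        if (ch < best) { best = ch; kind = 1; a1 = ax; a2 = f; }
      }
    }
    // rotations about world axes
    for (int ax = 0; ax < 3; ++ax) {
      for (int sgn = 0; sgn < 2; ++sgn) {
        double M[9], RR[9];
        axis_rot(ax, sgn ? -rot_deg : rot_deg, M);
        matmul3(M, R, RR);
        orthonormalise(RR);
        double ch = chamfer_placed(pts, unit_verts, c, s, RR);
        if (ch < best) { best = ch; kind = 2; a1 = ax; a2 = sgn; }
      }
    }
    double improvement = cur - best;
    if (kind == 0) {
      c[0] += step * tdir[a1][0];
      c[1] += step * tdir[a1][1];
      c[2] += step * tdir[a1][2];
      cur = best;
    } else if (kind == 1) {
      double ns_ = s[a1] * scale_factors[a2];
      if (ns_ < smin) ns_ = smin;
      if (ns_ > smax) ns_ = smax;
      s[a1] = ns_;
      cur = best;
    } else if (kind == 2) {
      double M[9], RR[9];
      axis_rot(a1, a2 ? -rot_deg : rot_deg, M);
      matmul3(M, R, RR);
      orthonormalise(RR);
      for (int i = 0; i < 9; ++i) R[i] = RR[i];
      cur = best;
    }
    trace.push_back(cur);
    if (cur < d_th1 || improvement < d_th2) break;
  }
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rout(i, j) = R[3 * i + j];
  return List::create(_["center"] = NumericVector::create(c[0], c[1], c[2]),
                      _["scales"] = NumericVector::create(s[0], s[1], s[2]),
                      _["rotation"] = Rout, _["chamfer"] = cur,
                      _["iterations"] = it, _["trace"] = wrap(trace));
}

// Hungarian algorithm (shortest augmenting path, O(n^3)) on a square cost
// matrix; returns the 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  const int n = cost.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// ---- point-in-mesh (ray parity) -------------------------------------------

// closest squared distance from point p to triangle (a, b, c) -- Ericson
static double point_tri_sqdist(const double p[3], const double a[3],
                               const double b[3], const double c[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  double q[3];
  if (d1 <= 0 && d2 <= 0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double t = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + t * ab[i];
      } else {
        double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
        double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
        if (d6 >= 0 && d5 <= d6) {
          q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double t = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) q[i] = a[i] + t * ac[i];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) q[i] = b[i] + t * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix points, NumericMatrix verts,
                                  IntegerMatrix faces) {
  const int n = points.nrow(), nf = faces.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double a[3] = {verts(faces(f, 0) - 1, 0), verts(faces(f, 0) - 1, 1),
                     verts(faces(f, 0) - 1, 2)};
      double b[3] = {verts(faces(f, 1) - 1, 0), verts(faces(f, 1) - 1, 1),
                     verts(faces(f, 1) - 1, 2)};
      double c[3] = {verts(faces(f, 2) - 1, 0), verts(faces(f, 2) - 1, 1),
                     verts(faces(f, 2) - 1, 2)};
      double d = point_tri_sqdist(p, a, b, c);
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Moeller-Trumbore; status 1 = hit, 0 = miss, -1 = degenerate/uncertain
static int ray_tri(const double o[3], const double d[3], const double v0[3],
                   const double v1[3], const double v2[3], double *tout) {
  const double EPS = 1e-10;
  double e1[3] = {v1[0] - v0[0], v1[1] - v0[1], v1[2] - v0[2]};
  double e2[3] = {v2[0] - v0[0], v2[1] - v0[1], v2[2] - v0[2]};
  double pv[3];
  cross3(d, e2, pv);
  double det = dot3(e1, pv);
  if (std::fabs(det) < 1e-14) return 0;  // parallel: no crossing contribution
  double inv = 1.0 / det;
  double tv[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
  double u = dot3(tv, pv) * inv;
  if (u < -EPS || u > 1 + EPS) return 0;
  double qv[3];
  cross3(tv, e1, qv);
  double v = dot3(d, qv) * inv;
  if (v < -EPS || u + v > 1 + EPS) return 0;
  double t = dot3(e2, qv) * inv;
  if (t <= EPS) return 0;
  // hits squarely inside the triangle are reliable; near-edge hits are not
  if (u < EPS || v < EPS || u + v > 1 - EPS) return -1;
  *tout = t;
  return 1;
}

// Strict inside test by ray-crossing parity.  Points closer than surf_tol to
// the surface count as on-surface (not inside).  Near-degenerate rays are
// retried along perturbed directions.
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix points, NumericMatrix verts,
                                 IntegerMatrix faces, double surf_tol) {
  const int n = points.nrow(), nf = faces.nrow();
  LogicalVector out(n);
  static const double dirs[5][3] = {{0.5773502692, 0.5784902692, 0.5750202692},
                                    {0.8017837257, 0.2672612419, 0.5345224838},
                                    {0.1230915, 0.9231862, 0.3641957},
                                    {-0.4850713, 0.7276069, 0.4850713},
                                    {0.3310069, -0.1655035, 0.9290197}};
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    // on-surface check
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double a[3] = {verts(faces(f, 0) - 1, 0), verts(faces(f, 0) - 1, 1),
                     verts(faces(f, 0) - 1, 2)};
      double b[3] = {verts(faces(f, 1) - 1, 0), verts(faces(f, 1) - 1, 1),
                     verts(faces(f, 1) - 1, 2)};
      double c[3] = {verts(faces(f, 2) - 1, 0), verts(faces(f, 2) - 1, 1),
                     verts(faces(f, 2) - 1, 2)};
      double d = point_tri_sqdist(p, a, b, c);
      if (d < best) best = d;
    }
    if (std::sqrt(best) <= surf_tol) {
      out[i] = false;
      continue;
    }
    bool decided = false;
    for (int trial = 0; trial < 5 && !decided; ++trial) {
      int crossings = 0;
      bool uncertain = false;
      for (int f = 0; f < nf && !uncertain; ++f) {
        double a[3] = {verts(faces(f, 0) - 1, 0), verts(faces(f, 0) - 1, 1),
                       verts(faces(f, 0) - 1, 2)};
        double b[3] = {verts(faces(f, 1) - 1, 0), verts(faces(f, 1) - 1, 1),
                       verts(faces(f, 1) - 1, 2)};
        double c[3] = {verts(faces(f, 2) - 1, 0), verts(faces(f, 2) - 1, 1),
                       verts(faces(f, 2) - 1, 2)};
        double t;
        int st = ray_tri(p, dirs[trial], a, b, c, &t);
        if (st == 1) ++crossings;
        else if (st == -1) uncertain = true;
      }
      if (!uncertain) {
        out[i] = (crossings % 2) == 1;
        decided = true;
      }
    }
    if (!decided) out[i] = false;  // all rays degenerate: treat as outside
  }
  return out;
}
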