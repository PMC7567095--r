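// Analytic boundary-element kernels for linear-collocation BEM.
//
// Conventions: positions in metres, triangles planar with outward unit
// normals from the winding order. The double-layer kernel is
//   K(x, y) = (y - x) . n(y) / |y - x|^3,
// whose triangle integrals are solid angles; with a linear (hat) basis the
// element integrals reduce to the van Oosterom-Strackee solid angle plus
// analytic edge log terms (first moment of the solid-angle kernel).
// Inner loops are written in plain scalar arithmetic: the assembly cost is
// collocation-points x triangles and dominates model building.

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 v3(double x, double y, double z) { V3 v{x, y, z}; return v; }
static inline V3 sub(const V3& a, const V3& b) {
  return v3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline double dot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 scale(const V3& a, double s) {
  return v3(a.x * s, a.y * s, a.z * s);
}

struct TriPre {
  V3 p1, p2, p3;   // vertices
  V3 n;            // unit normal
  V3 g1, g2, g3;   // in-plane hat-function gradients
  V3 m12, m23, m31;  // outward in-plane edge normals
  double a1, a2, a3; // affine offsets: psi_l(y) = a_l + g_l . y
  int i1, i2, i3;    // 0-based vertex indices
};

static std::vector<TriPre> precompute(const NumericMatrix& V,
                                      const IntegerMatrix& F) {
  std::vector<TriPre> out(F.nrow());
  for (int t = 0; t < F.nrow(); ++t) {
    TriPre tp;
    tp.i1 = F(t, 0) - 1; tp.i2 = F(t, 1) - 1; tp.i3 = F(t, 2) - 1;
    tp.p1 = v3(V(tp.i1, 0), V(tp.i1, 1), V(tp.i1, 2));
    tp.p2 = v3(V(tp.i2, 0), V(tp.i2, 1), V(tp.i2, 2));
    tp.p3 = v3(V(tp.i3, 0), V(tp.i3, 1), V(tp.i3, 2));
    V3 e12 = sub(tp.p2, tp.p1), e23 = sub(tp.p3, tp.p2),
      e31 = sub(tp.p1, tp.p3);
    V3 cr = cross(e12, sub(tp.p3, tp.p1));
    double a2 = norm3(cr);
    tp.n = a2 > 0 ? scale(cr, 1.0 / a2) : v3(0, 0, 0);
    tp.g1 = scale(cross(tp.n, e23), 1.0 / a2);
    tp.g2 = scale(cross(tp.n, scale(e31, 1.0)), 1.0 / a2);
    tp.g3 = scale(cross(tp.n, e12), 1.0 / a2);
    tp.a1 = 1.0 - dot(tp.g1, tp.p1);
    tp.a2 = 1.0 - dot(tp.g2, tp.p2);
    tp.a3 = 1.0 - dot(tp.g3, tp.p3);
    V3 u;
    u = cross(e12, tp.n); tp.m12 = scale(u, 1.0 / norm3(u));
    u = cross(e23, tp.n); tp.m23 = scale(u, 1.0 / norm3(u));
    u = cross(e31, tp.n); tp.m31 = scale(u, 1.0 / norm3(u));
    out[t] = tp;
  }
  return out;
}

static inline double edge_log(const V3& A, const V3& B, const V3& x) {
  V3 d = sub(B, A);
  double L = norm3(d);
  if (L < 1e-300) return 0.0;
  double inv = 1.0 / L;
  V3 s = scale(d, inv);
  V3 ax = sub(A, x), bx = sub(B, x);
  double sA = dot(ax, s), sB = dot(bx, s);
  double RA = norm3(ax), RB = norm3(bx);
  double num = RB + sB, den = RA + sA;
  if (num < 1e-14 || den < 1e-14) {
    num = RA - sA;  // equivalent expression, stable on the other side
    den = RB - sB;
    if (num < 1e-14 || den < 1e-14) return 0.0;
  }
  return std::log(num / den);
}

// signed solid angle of a triangle seen from x (van Oosterom-Strackee);
// positive when x is on the inner side of an outward-oriented surface
static inline double solid_angle_tri(const TriPre& tp, const V3& x) {
  V3 w1 = sub(tp.p1, x), w2 = sub(tp.p2, x), w3 = sub(tp.p3, x);
  double r1 = norm3(w1), r2 = norm3(w2), r3 = norm3(w3);
  double num = dot(w1, cross(w2, w3));
  double den = r1 * r2 * r3 + dot(w1, w2) * r3 + dot(w1, w3) * r2 +
    dot(w2, w3) * r1;
  return 2.0 * std::atan2(num, den);
}

// element integrals int psi_l dOmega of one triangle seen from x
static inline void element_integrals(const TriPre& tp, const V3& x,
                                     double& c1, double& c2, double& c3) {
  double h = dot(tp.n, sub(tp.p1, x));
  double om = solid_angle_tri(tp, x);
  double gj1 = 0, gj2 = 0, gj3 = 0;
  if (std::abs(h) > 1e-14) {
    double l12 = edge_log(tp.p1, tp.p2, x);
    double l23 = edge_log(tp.p2, tp.p3, x);
    double l31 = edge_log(tp.p3, tp.p1, x);
    // J1 = int (y - x)/R^3 dS = -(sum_e log_e m_e) + n * Omega
    V3 J1 = v3(-(l12 * tp.m12.x + l23 * tp.m23.x + l31 * tp.m31.x) + tp.n.x * om,
               -(l12 * tp.m12.y + l23 * tp.m23.y + l31 * tp.m31.y) + tp.n.y * om,
               -(l12 * tp.m12.z + l23 * tp.m23.z + l31 * tp.m31.z) + tp.n.z * om);
    gj1 = dot(tp.g1, J1); gj2 = dot(tp.g2, J1); gj3 = dot(tp.g3, J1);
  }
  c1 = (tp.a1 + dot(tp.g1, x)) * om + h * gj1;
  c2 = (tp.a2 + dot(tp.g2, x)) * om + h * gj2;
  c3 = (tp.a3 + dot(tp.g3, x)) * om + h * gj3;
}

// Double-layer matrix: D(i, j) = int_S psi_j(y) (y - x_i).n(y)/|y-x_i|^3 dS
// over the whole surface (V, F). Rows: collocation points X; columns:
// surface vertices.
// [[Rcpp::export(name = ".assemble_double_layer_cpp")]]
NumericMatrix assemble_double_layer_cpp(NumericMatrix X, NumericMatrix V,
                                        IntegerMatrix F) {
  std::vector<TriPre> pre = precompute(V, F);
  NumericMatrix D(X.nrow(), V.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    V3 x = v3(X(i, 0), X(i, 1), X(i, 2));
    for (size_t t = 0; t < pre.size(); ++t) {
      double c1, c2, c3;
      element_integrals(pre[t], x, c1, c2, c3);
      D(i, pre[t].i1) += c1;
      D(i, pre[t].i2) += c2;
      D(i, pre[t].i3) += c3;
    }
  }
  return D;
}

// Assemble scale * D into the column block of a preallocated big matrix A
// (no N x N temporary): A(i, col_offset + j) += scale * D_ij. Returns the
// unscaled row sums of the block (total solid angle of this surface seen
// from each collocation point), used for the closure correction of the
// diagonal.
// [[Rcpp::export(name = ".assemble_double_layer_into_cpp")]]
NumericVector assemble_double_layer_into_cpp(NumericMatrix A, int col_offset,
                                             double scale, NumericMatrix X,
                                             NumericMatrix V,
                                             IntegerMatrix F) {
  std::vector<TriPre> pre = precompute(V, F);
  int n = X.nrow();
  NumericVector rs(n);
  double* a = A.begin();
  R_xlen_t lda = A.nrow();
  for (int i = 0; i < n; ++i) {
    V3 x = v3(X(i, 0), X(i, 1), X(i, 2));
    double acc = 0;
    for (size_t t = 0; t < pre.size(); ++t) {
      double c1, c2, c3;
      element_integrals(pre[t], x, c1, c2, c3);
      acc += c1 + c2 + c3;
      a[(R_xlen_t)(col_offset + pre[t].i1) * lda + i] += scale * c1;
      a[(R_xlen_t)(col_offset + pre[t].i2) * lda + i] += scale * c2;
      a[(R_xlen_t)(col_offset + pre[t].i3) * lda + i] += scale * c3;
    }
    rs[i] = acc;
  }
  return rs;
}

// Solid angle of the whole surface seen from each point (row sums of the
// double-layer matrix without assembling it).
// [[Rcpp::export(name = ".surface_solid_angle_cpp")]]
NumericVector surface_solid_angle_cpp(NumericMatrix X, NumericMatrix V,
                                      IntegerMatrix F) {
  std::vector<TriPre> pre = precompute(V, F);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    V3 x = v3(X(i, 0), X(i, 1), X(i, 2));
    double s = 0;
    for (size_t t = 0; t < pre.size(); ++t)
      s += solid_angle_tri(pre[t], x);
    out[i] = s;
  }
  return out;
}

// In-place rank-one deflation: A += val (every entry).
// [[Rcpp::export(name = ".add_constant_inplace_cpp")]]
void add_constant_inplace_cpp(NumericMatrix A, double val) {
  R_xlen_t n = (R_xlen_t)A.nrow() * A.ncol();
  double* p = A.begin();
  for (R_xlen_t i = 0; i < n; ++i) p[i] += val;
}

// quadrature points/weights of a triangle for the magnetic surface
// integrals: 1-point (centroid) or 3-point (edge midpoints), linear basis
struct QuadT {
  V3 q[3];
  double f[3];       // interpolated phi (B integral) at the points
  double bw[3][3];   // basis weights (flux functional)
  double w[3];
  int nq;
};

static inline QuadT tri_quad(const V3& p1, const V3& p2, const V3& p3,
                             double f1, double f2, double f3, double area,
                             int quad_points) {
  QuadT qd;
  if (quad_points == 3) {
    qd.nq = 3;
    qd.q[0] = scale(v3(p1.x + p2.x, p1.y + p2.y, p1.z + p2.z), 0.5);
    qd.q[1] = scale(v3(p2.x + p3.x, p2.y + p3.y, p2.z + p3.z), 0.5);
    qd.q[2] = scale(v3(p3.x + p1.x, p3.y + p1.y, p3.z + p1.z), 0.5);
    qd.f[0] = 0.5 * (f1 + f2); qd.f[1] = 0.5 * (f2 + f3);
    qd.f[2] = 0.5 * (f3 + f1);
    double bw[3][3] = {{0.5, 0.5, 0.0}, {0.0, 0.5, 0.5}, {0.5, 0.0, 0.5}};
    for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b)
      qd.bw[a][b] = bw[a][b];
    qd.w[0] = qd.w[1] = qd.w[2] = area / 3;
  } else {
    qd.nq = 1;
    qd.q[0] = scale(v3(p1.x + p2.x + p3.x, p1.y + p2.y + p3.y,
                       p1.z + p2.z + p3.z), 1.0 / 3);
    qd.f[0] = (f1 + f2 + f3) / 3;
    qd.bw[0][0] = qd.bw[0][1] = qd.bw[0][2] = 1.0 / 3;
    qd.w[0] = area;
  }
  return qd;
}

// Surface term of the Geselowitz magnetic-field formula, without the
// (mu0/4pi)(sigma- - sigma+) prefactor:
//   B_surf(r) = int_S phi(y) n(y) x (r - y)/|r - y|^3 dS.
// [[Rcpp::export(name = ".geselowitz_surface_B_cpp")]]
NumericMatrix geselowitz_surface_B_cpp(NumericMatrix V, IntegerMatrix F,
                                       NumericVector phi, NumericMatrix R,
                                       int quad_points) {
  NumericMatrix out(R.nrow(), 3);
  for (int t = 0; t < F.nrow(); ++t) {
    int i1 = F(t, 0) - 1, i2 = F(t, 1) - 1, i3 = F(t, 2) - 1;
    V3 p1 = v3(V(i1, 0), V(i1, 1), V(i1, 2));
    V3 p2 = v3(V(i2, 0), V(i2, 1), V(i2, 2));
    V3 p3 = v3(V(i3, 0), V(i3, 1), V(i3, 2));
    V3 cr = cross(sub(p2, p1), sub(p3, p1));
    double a2 = norm3(cr);
    if (a2 <= 0) continue;
    V3 n = scale(cr, 1.0 / a2);
    QuadT qd = tri_quad(p1, p2, p3, phi[i1], phi[i2], phi[i3], a2 / 2,
                        quad_points);
    for (int k = 0; k < R.nrow(); ++k) {
      V3 r = v3(R(k, 0), R(k, 1), R(k, 2));
      for (int m = 0; m < qd.nq; ++m) {
        V3 d = sub(r, qd.q[m]);
        double r2 = dot(d, d);
        double s = qd.f[m] * qd.w[m] / (r2 * std::sqrt(r2));
        V3 nc = cross(n, d);
        out(k, 0) += s * nc.x; out(k, 1) += s * nc.y; out(k, 2) += s * nc.z;
      }
    }
  }
  return out;
}

// Flux functional: g with g . phi = sum_k int_S phi(y)
//   [n(y) x (r_k - y)/|r_k - y|^3] . (w_k m_k) dS,
// rows of C are coil dipole positions, rows of WM are w_k * m_k (m^2).
// [[Rcpp::export(name = ".geselowitz_flux_vector_cpp")]]
NumericVector geselowitz_flux_vector_cpp(NumericMatrix V, IntegerMatrix F,
                                         NumericMatrix C, NumericMatrix WM,
                                         int quad_points) {
  NumericVector g(V.nrow());
  int nk = C.nrow();
  for (int t = 0; t < F.nrow(); ++t) {
    int i1 = F(t, 0) - 1, i2 = F(t, 1) - 1, i3 = F(t, 2) - 1;
    V3 p1 = v3(V(i1, 0), V(i1, 1), V(i1, 2));
    V3 p2 = v3(V(i2, 0), V(i2, 1), V(i2, 2));
    V3 p3 = v3(V(i3, 0), V(i3, 1), V(i3, 2));
    V3 cr = cross(sub(p2, p1), sub(p3, p1));
    double a2 = norm3(cr);
    if (a2 <= 0) continue;
    V3 n = scale(cr, 1.0 / a2);
    QuadT qd = tri_quad(p1, p2, p3, 0, 0, 0, a2 / 2, quad_points);
    for (int m = 0; m < qd.nq; ++m) {
      double s = 0;
      for (int k = 0; k < nk; ++k) {
        V3 d = v3(C(k, 0) - qd.q[m].x, C(k, 1) - qd.q[m].y,
                  C(k, 2) - qd.q[m].z);
        double r2 = dot(d, d);
        V3 nc = cross(n, d);
        s += (nc.x * WM(k, 0) + nc.y * WM(k, 1) + nc.z * WM(k, 2)) /
          (r2 * std::sqrt(r2));
      }
      s *= qd.w[m];
      g[i1] += s * qd.bw[m][0];
      g[i2] += s * qd.bw[m][1];
      g[i3] += s * qd.bw[m][2];
    }
  }
  return g;
}
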