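// Voxel-volume primitives: exact Euclidean distance transform (used for
// morphology with a spherical structuring element), 26-connected component
// labelling, marching-tetrahedra iso-surface extraction, and brute-force
// point-to-mesh distance.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// --- 1D squared distance transform (Felzenszwalb & Huttenlocher) ---------
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
        (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from every voxel to the nearest
// TRUE voxel of `mask` (dims nx, ny, nz).
// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : 1e300;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x direction
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y direction
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // z direction
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k)
        f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k)
        out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// 26-connected component labelling of a binary volume. Labels start at 1;
// background is 0. Returns an integer vector of the same length.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(seed);
    lab[seed] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx;
      int j = (cur / nx) % ny;
      int k = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz) continue;
            R_xlen_t idx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[idx] && lab[idx] == 0) {
              lab[idx] = next;
              stack.push_back(idx);
            }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// --- marching tetrahedra -------------------------------------------------
// Iso-surface of a scalar volume at level `iso`, in voxel-index
// coordinates (0-based, x fastest). Each cube is decomposed into 6
// tetrahedra sharing the main diagonal; interface vertices are linearly
// interpolated along tet edges and welded through a global edge key.
// Triangles are wound so normals point away from the super-level set
// (val > iso), i.e. outward for object masks.

struct MTState {
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> verts;   // xyz triplets
  std::vector<int> tris;       // 1-based triplets
};

static int interp_vertex(MTState& st, const NumericVector& vol,
                         R_xlen_t ia, R_xlen_t ib,
                         const double* pa, const double* pb, double iso) {
  uint64_t key = ia < ib
    ? ((uint64_t)ia << 32) | (uint64_t)ib
    : ((uint64_t)ib << 32) | (uint64_t)ia;
  auto it = st.vmap.find(key);
  if (it != st.vmap.end()) return it->second;
  double va = vol[ia], vb = vol[ib];
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  st.verts.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.verts.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.verts.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)(st.verts.size() / 3);  // 1-based
  st.vmap.emplace(key, id);
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     const double* inside_pt) {
  // orient so the normal points away from inside_pt (the > iso side)
  const double* A = &st.verts[(a - 1) * 3];
  const double* B = &st.verts[(b - 1) * 3];
  const double* C = &st.verts[(c - 1) * 3];
  double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double w[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
  double nx = u[1] * w[2] - u[2] * w[1];
  double ny = u[2] * w[0] - u[0] * w[2];
  double nz = u[0] * w[1] - u[1] * w[0];
  double cx = (A[0] + B[0] + C[0]) / 3 - inside_pt[0];
  double cy = (A[1] + B[1] + C[1]) / 3 - inside_pt[1];
  double cz = (A[2] + B[2] + C[2]) / 3 - inside_pt[2];
  if (nx * cx + ny * cy + nz * cz < 0) std::swap(b, c);
  st.tris.push_back(a);
  st.tris.push_back(b);
  st.tris.push_back(c);
}

// [[Rcpp::export(name = ".marching_tetrahedra_cpp")]]
List marching_tetrahedra_cpp(NumericVector vol, IntegerVector dims,
                             double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  MTState st;
  // cube corner offsets (x, y, z)
  static const int co[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // 6 tetrahedra sharing diagonal corner0-corner6
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t cidx[8];
        double cpos[8][3];
        double cval[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int xi = i + co[c][0], yj = j + co[c][1], zk = k + co[c][2];
          cidx[c] = (R_xlen_t)zk * nx * ny + (R_xlen_t)yj * nx + xi;
          cval[c] = vol[cidx[c]];
          cpos[c][0] = xi; cpos[c][1] = yj; cpos[c][2] = zk;
          if (cval[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int tt = 0; tt < 6; ++tt) {
          int vI[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = tets[tt][c];
            if (cval[cc] > iso) vI[nin++] = cc;
          }
          if (nin == 0 || nin == 4) continue;
          int in_[4], out_[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = tets[tt][c];
            if (cval[cc] > iso) in_[ni++] = cc; else out_[no++] = cc;
          }
          if (ni == 1) {
            int a = interp_vertex(st, vol, cidx[in_[0]], cidx[out_[0]],
                                  cpos[in_[0]], cpos[out_[0]], iso);
            int b = interp_vertex(st, vol, cidx[in_[0]], cidx[out_[1]],
                                  cpos[in_[0]], cpos[out_[1]], iso);
            int c = interp_vertex(st, vol, cidx[in_[0]], cidx[out_[2]],
                                  cpos[in_[0]], cpos[out_[2]], iso);
            emit_tri(st, a, b, c, cpos[in_[0]]);
          } else if (ni == 3) {
            int a = interp_vertex(st, vol, cidx[out_[0]], cidx[in_[0]],
                                  cpos[out_[0]], cpos[in_[0]], iso);
            int b = interp_vertex(st, vol, cidx[out_[0]], cidx[in_[1]],
                                  cpos[out_[0]], cpos[in_[1]], iso);
            int c = interp_vertex(st, vol, cidx[out_[0]], cidx[in_[2]],
                                  cpos[out_[0]], cpos[in_[2]], iso);
            double mid[3] = {
              (cpos[in_[0]][0] + cpos[in_[1]][0] + cpos[in_[2]][0]) / 3,
              (cpos[in_[0]][1] + cpos[in_[1]][1] + cpos[in_[2]][1]) / 3,
              (cpos[in_[0]][2] + cpos[in_[1]][2] + cpos[in_[2]][2]) / 3};
            emit_tri(st, a, b, c, mid);
          } else {  // ni == 2: quad split into two triangles
            int a = interp_vertex(st, vol, cidx[in_[0]], cidx[out_[0]],
                                  cpos[in_[0]], cpos[out_[0]], iso);
            int b = interp_vertex(st, vol, cidx[in_[0]], cidx[out_[1]],
                                  cpos[in_[0]], cpos[out_[1]], iso);
            int c = interp_vertex(st, vol, cidx[in_[1]], cidx[out_[0]],
                                  cpos[in_[1]], cpos[out_[0]], iso);
            int d = interp_vertex(st, vol, cidx[in_[1]], cidx[out_[1]],
                                  cpos[in_[1]], cpos[out_[1]], iso);
            double mid[3] = {
              (cpos[in_[0]][0] + cpos[in_[1]][0]) / 2,
              (cpos[in_[0]][1] + cpos[in_[1]][1]) / 2,
              (cpos[in_[0]][2] + cpos[in_[1]][2]) / 2};
            emit_tri(st, a, b, c, mid);
            emit_tri(st, c, b, d, mid);
          }
        }
      }
  NumericMatrix V(st.verts.size() / 3, 3);
  for (R_xlen_t r = 0; r < V.nrow(); ++r) {
    V(r, 0) = st.verts[r * 3];
    V(r, 1) = st.verts[r * 3 + 1];
    V(r, 2) = st.verts[r * 3 + 2];
  }
  IntegerMatrix T(st.tris.size() / 3, 3);
  for (R_xlen_t r = 0; r < T.nrow(); ++r) {
    T(r, 0) = st.tris[r * 3];
    T(r, 1) = st.tris[r * 3 + 1];
    T(r, 2) = st.tris[r * 3 + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = T);
}

// --- point to triangle-mesh distance -------------------------------------
static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist2 = [&](double x, double y, double z) {
    double dx = p[0] - x, dy = p[1] - y, dz = p[2] - z;
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a[0], a[1], a[2]);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b[0], b[1], b[2]);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2(a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(c[0], c[1], c[2]);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2(a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                 b[2] + w * (c[2] - b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2(a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
               a[2] + ab[2] * v + ac[2] * w);
}

// Distance from each point (rows of P) to the closest point on the mesh.
// [[Rcpp::export(name = ".point_mesh_distance_cpp")]]
NumericVector point_mesh_distance_cpp(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  R_xlen_t np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  // triangle bounding boxes for cheap pruning
  std::vector<double> bb(nf * 6);
  for (R_xlen_t t = 0; t < nf; ++t) {
    for (int d = 0; d < 3; ++d) {
      double x1 = V(F(t, 0) - 1, d), x2 = V(F(t, 1) - 1, d),
        x3 = V(F(t, 2) - 1, d);
      bb[t * 6 + d] = std::min(x1, std::min(x2, x3));
      bb[t * 6 + 3 + d] = std::max(x1, std::max(x2, x3));
    }
  }
  for (R_xlen_t p = 0; p < np; ++p) {
    double pt[3] = {P(p, 0), P(p, 1), P(p, 2)};
    double best = 1e300;
    for (R_xlen_t t = 0; t < nf; ++t) {
      // lower bound via bbox
      double lb = 0;
      for (int d = 0; d < 3; ++d) {
        double lo = bb[t * 6 + d], hi = bb[t * 6 + 3 + d];
        double e = pt[d] < lo ? lo - pt[d] : (pt[d] > hi ? pt[d] - hi : 0);
        lb += e * e;
      }
      if (lb >= best) continue;
      double a[3] = {V(F(t, 0) - 1, 0), V(F(t, 0) - 1, 1), V(F(t, 0) - 1, 2)};
      double b[3] = {V(F(t, 1) - 1, 0), V(F(t, 1) - 1, 1), V(F(t, 1) - 1, 2)};
      double c[3] = {V(F(t, 2) - 1, 0), V(F(t, 2) - 1, 1), V(F(t, 2) - 1, 2)};
      double d2 = point_tri_dist2(pt, a, b, c);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// --- mesh voxelisation ---------------------------------------------------
// Parity fill of a closed mesh on a voxel grid: for every (x, y) voxel
// column the z-crossings with the surface are collected and voxels between
// odd/even crossing pairs are marked inside. Grid coordinates: voxel (i,j,k)
// has world position origin + spacing * (i,j,k).
// [[Rcpp::export(name = ".voxelize_mesh_cpp")]]
LogicalVector voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double spacing,
                                IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  const double eps = 1e-9;
  for (R_xlen_t t = 0; t < F.nrow(); ++t) {
    double a[3] = {V(F(t, 0) - 1, 0), V(F(t, 0) - 1, 1), V(F(t, 0) - 1, 2)};
    double b[3] = {V(F(t, 1) - 1, 0), V(F(t, 1) - 1, 1), V(F(t, 1) - 1, 2)};
    double c[3] = {V(F(t, 2) - 1, 0), V(F(t, 2) - 1, 1), V(F(t, 2) - 1, 2)};
    double xmin = std::min(a[0], std::min(b[0], c[0]));
    double xmax = std::max(a[0], std::max(b[0], c[0]));
    double ymin = std::min(a[1], std::min(b[1], c[1]));
    double ymax = std::max(a[1], std::max(b[1], c[1]));
    int i0 = std::max(0, (int)std::ceil((xmin - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - origin[1]) / spacing));
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + spacing * j + eps;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + spacing * i + eps;
        // 2D barycentric test in the xy plane
        double d = (b[1] - c[1]) * (a[0] - c[0]) +
          (c[0] - b[0]) * (a[1] - c[1]);
        if (std::abs(d) < 1e-300) continue;
        double w1 = ((b[1] - c[1]) * (px - c[0]) +
                     (c[0] - b[0]) * (py - c[1])) / d;
        double w2 = ((c[1] - a[1]) * (px - c[0]) +
                     (a[0] - c[0]) * (py - c[1])) / d;
        double w3 = 1.0 - w1 - w2;
        if (w1 < 0 || w2 < 0 || w3 < 0) continue;
        double z = w1 * a[2] + w2 * b[2] + w3 * c[2];
        cross[(size_t)j * nx + i].push_back(z);
      }
    }
  }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& zs = cross[(size_t)j * nx + i];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // collapse duplicate crossings from shared triangle edges
      std::vector<double> zu;
      for (double z : zs) {
        if (!zu.empty() && std::abs(z - zu.back()) < 1e-9) {
          zu.pop_back();  // even multiplicity cancels
        } else zu.push_back(z);
      }
      if (zu.size() % 2 != 0) continue;  // grazing contact; skip column
      for (size_t p = 0; p + 1 < zu.size(); p += 2) {
        int k0 = std::max(0, (int)std::ceil((zu[p] - origin[2]) / spacing));
        int k1 = std::min(nz - 1,
                          (int)std::floor((zu[p + 1] - origin[2]) / spacing));
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
      }
    }
  return out;
}

// Grid-accelerated point-to-mesh distance: triangles are binned by their
// bounding boxes into a uniform grid; each query scans cells in expanding
// shells until the current best distance is provably minimal.
// [[Rcpp::export(name = ".point_mesh_distance_grid_cpp")]]
NumericVector point_mesh_distance_grid_cpp(NumericMatrix P, NumericMatrix V,
                                           IntegerMatrix F, double cell) {
  R_xlen_t np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (R_xlen_t v = 0; v < V.nrow(); ++v) {
      lo[d] = std::min(lo[d], V(v, d));
      hi[d] = std::max(hi[d], V(v, d));
    }
  }
  int n[3];
  for (int d = 0; d < 3; ++d)
    n[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / cell));
  auto clampi = [](int x, int nmax) {
    return std::max(0, std::min(nmax - 1, x));
  };
  std::vector<std::vector<int>> bins((size_t)n[0] * n[1] * n[2]);
  for (R_xlen_t t = 0; t < nf; ++t) {
    double bmin[3], bmax[3];
    for (int d = 0; d < 3; ++d) {
      double x1 = V(F(t, 0) - 1, d), x2 = V(F(t, 1) - 1, d),
        x3 = V(F(t, 2) - 1, d);
      bmin[d] = std::min(x1, std::min(x2, x3));
      bmax[d] = std::max(x1, std::max(x2, x3));
    }
    int i0 = clampi((int)((bmin[0] - lo[0]) / cell), n[0]);
    int i1 = clampi((int)((bmax[0] - lo[0]) / cell), n[0]);
    int j0 = clampi((int)((bmin[1] - lo[1]) / cell), n[1]);
    int j1 = clampi((int)((bmax[1] - lo[1]) / cell), n[1]);
    int k0 = clampi((int)((bmin[2] - lo[2]) / cell), n[2]);
    int k1 = clampi((int)((bmax[2] - lo[2]) / cell), n[2]);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          bins[((size_t)k * n[1] + j) * n[0] + i].push_back((int)t);
  }
  int nmaxshell = std::max(n[0], std::max(n[1], n[2]));
  for (R_xlen_t p = 0; p < np; ++p) {
    double pt[3] = {P(p, 0), P(p, 1), P(p, 2)};
    int ci = clampi((int)((pt[0] - lo[0]) / cell), n[0]);
    int cj = clampi((int)((pt[1] - lo[1]) / cell), n[1]);
    int ck = clampi((int)((pt[2] - lo[2]) / cell), n[2]);
    double best = 1e300;
    for (int s = 0; s <= nmaxshell; ++s) {
      // once a hit is found, one extra shell guarantees the true minimum
      if (best < 1e300) {
        double safe = (double)(s - 1) * cell;
        if (safe > 0 && best <= safe * safe) break;
      }
      bool any_cell = false;
      for (int k = ck - s; k <= ck + s; ++k) {
        if (k < 0 || k >= n[2]) continue;
        for (int j = cj - s; j <= cj + s; ++j) {
          if (j < 0 || j >= n[1]) continue;
          for (int i = ci - s; i <= ci + s; ++i) {
            if (i < 0 || i >= n[0]) continue;
            if (s > 0 && std::abs(i - ci) != s && std::abs(j - cj) != s &&
                std::abs(k - ck) != s) continue;  // interior already done
            any_cell = true;
            const std::vector<int>& tri =
              bins[((size_t)k * n[1] + j) * n[0] + i];
            for (int t : tri) {
              double a[3] = {V(F(t, 0) - 1, 0), V(F(t, 0) - 1, 1),
                             V(F(t, 0) - 1, 2)};
              double b[3] = {V(F(t, 1) - 1, 0), V(F(t, 1) - 1, 1),
                             V(F(t, 1) - 1, 2)};
              double c[3] = {V(F(t, 2) - 1, 0), V(F(t, 2) - 1, 1),
                             V(F(t, 2) - 1, 2)};
              double d2 = point_tri_dist2(pt, a, b, c);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      (void)any_cell;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
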