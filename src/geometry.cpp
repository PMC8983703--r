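#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

// Signed distance to the union of atom spheres, sampled on a regular grid:
// d(x) = min_i ( |x - c_i| - r_i ).  Each atom only touches grid nodes within
// r_i + reach of its center; nodes outside every atom's reach keep a large
// positive value, which is sign-correct (outside) for iso levels < reach.
// [[Rcpp::export]]
NumericVector sphere_field_cpp(NumericMatrix centers, NumericVector radii,
                               NumericVector origin, double spacing,
                               IntegerVector dims, double reach) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz, 1e9);
  const int na = centers.nrow();
  for (int a = 0; a < na; ++a) {
    const double cx = centers(a, 0), cy = centers(a, 1), cz = centers(a, 2);
    const double rr = radii[a] + reach;
    const int i0 = std::max(0, (int)std::floor((cx - rr - origin[0]) / spacing));
    const int i1 = std::min(nx - 1, (int)std::ceil((cx + rr - origin[0]) / spacing));
    const int j0 = std::max(0, (int)std::floor((cy - rr - origin[1]) / spacing));
    const int j1 = std::min(ny - 1, (int)std::ceil((cy + rr - origin[1]) / spacing));
    const int k0 = std::max(0, (int)std::floor((cz - rr - origin[2]) / spacing));
    const int k1 = std::min(nz - 1, (int)std::ceil((cz + rr - origin[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - cy;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - cx;
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
          if (d < out[base + i]) out[base + i] = d;
        }
      }
    }
  }
  return out;
}

// Marching tetrahedra over a scalar field.  Each grid cube is split into six
// tetrahedra fanned around its main diagonal; the face diagonals this induces
// are consistent between neighbouring cubes, so the extracted surface is
// closed (watertight) for iso-surfaces away from the grid boundary.
// "Inside" is field < iso (strict); vertices are placed by linear
// interpolation on cube edges and deduplicated by edge identity.
// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector dims,
                             NumericVector origin, double spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int tets[6][4] = {{0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
                                 {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}};
  std::map<std::pair<R_xlen_t, R_xlen_t>, int> edge_map;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa_, fb_, fc_;

  auto vertex_on_edge = [&](R_xlen_t ga, R_xlen_t gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    std::pair<R_xlen_t, R_xlen_t> key(ga, gb);
    std::map<std::pair<R_xlen_t, R_xlen_t>, int>::iterator it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    const double f1 = field[ga], f2 = field[gb];
    double t = (f2 == f1) ? 0.5 : (iso - f1) / (f2 - f1);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    const int ia = (int)(ga % nx), ja = (int)((ga / nx) % ny), ka = (int)(ga / ((R_xlen_t)nx * ny));
    const int ib = (int)(gb % nx), jb = (int)((gb / nx) % ny), kb = (int)(gb / ((R_xlen_t)nx * ny));
    vx.push_back(origin[0] + spacing * (ia + t * (ib - ia)));
    vy.push_back(origin[1] + spacing * (ja + t * (jb - ja)));
    vz.push_back(origin[2] + spacing * (ka + t * (kb - ka)));
    const int id = (int)vx.size() - 1;
    edge_map[key] = id;
    return id;
  };
  auto add_face = [&](int a, int b, int c) {
    fa_.push_back(a); fb_.push_back(b); fc_.push_back(c);
  };

  R_xlen_t g[8];
  bool in[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          const int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          g[c] = (R_xlen_t)ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck);
          in[c] = field[g[c]] < iso;
          n_in += in[c];
        }
        if (n_in == 0 || n_in == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            const int c = tets[t][v];
            if (in[c]) ins[ni++] = c; else outs[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1) {
            add_face(vertex_on_edge(g[ins[0]], g[outs[0]]),
                     vertex_on_edge(g[ins[0]], g[outs[1]]),
                     vertex_on_edge(g[ins[0]], g[outs[2]]));
          } else if (ni == 3) {
            add_face(vertex_on_edge(g[outs[0]], g[ins[0]]),
                     vertex_on_edge(g[outs[0]], g[ins[1]]),
                     vertex_on_edge(g[outs[0]], g[ins[2]]));
          } else {  // 2 in, 2 out: quad split into two triangles
            const int v1 = vertex_on_edge(g[ins[0]], g[outs[0]]);
            const int v2 = vertex_on_edge(g[ins[0]], g[outs[1]]);
            const int v3 = vertex_on_edge(g[ins[1]], g[outs[1]]);
            const int v4 = vertex_on_edge(g[ins[1]], g[outs[0]]);
            add_face(v1, v2, v3);
            add_face(v1, v3, v4);
          }
        }
      }
    }
  }

  const int nv = (int)vx.size(), nf = (int)fa_.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  IntegerMatrix Fm(nf, 3);
  for (int f = 0; f < nf; ++f) {  // 1-based for R
    Fm(f, 0) = fa_[f] + 1; Fm(f, 1) = fb_[f] + 1; Fm(f, 2) = fc_[f] + 1;
  }
  return List::create(Named("vertices") = V, Named("faces") = Fm);
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Squared distance from point p to triangle (a, b, c); Ericson's
// closest-point-on-triangle region test.
static double pt_tri_dist2(const double* p, const double* a, const double* b,
                           const double* c) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) { ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d]; }
  const double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return dot3(ap, ap);

  double bp[3];
  for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
  const double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return dot3(bp, bp);

  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    double q[3];
    for (int d = 0; d < 3; ++d) q[d] = ap[d] - v * ab[d];
    return dot3(q, q);
  }

  double cp[3];
  for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
  const double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return dot3(cp, cp);

  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    double q[3];
    for (int d = 0; d < 3; ++d) q[d] = ap[d] - w * ac[d];
    return dot3(q, q);
  }

  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3];
    for (int d = 0; d < 3; ++d) q[d] = bp[d] - w * (c[d] - b[d]);
    return dot3(q, q);
  }

  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  double q[3];
  for (int d = 0; d < 3; ++d) q[d] = ap[d] - (v * ab[d] + w * ac[d]);
  return dot3(q, q);
}

// [[Rcpp::export]]
NumericVector point_triangle_dist_cpp(NumericMatrix P, NumericVector a,
                                      NumericVector b, NumericVector c) {
  const int n = P.nrow();
  NumericVector out(n);
  double aa[3] = {a[0], a[1], a[2]}, bb[3] = {b[0], b[1], b[2]}, cc[3] = {c[0], c[1], c[2]};
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    out[i] = std::sqrt(pt_tri_dist2(p, aa, bb, cc));
  }
  return out;
}

// Binary surface voxelization: a voxel is 1 iff the distance from its center
// to the nearest mesh triangle is < cutoff * spacing (strict).  The grid is
// isotropic and centered on the vertex centroid; the spacing is derived from
// twice the maximum vertex-to-centroid distance, a rotation-invariant size
// measure that bounds the bounding-box extent, so the shell thickness
// (cutoff grid intervals) does not depend on the object's orientation and
// the mesh always fits with at least the cutoff + 1 voxel margin.  Each
// triangle only visits voxels inside its bounding box expanded by the
// cutoff distance, which covers every voxel it can mark.
// [[Rcpp::export]]
List voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix Fm, int N, double cutoff,
                       NumericVector center = NumericVector::create(),
                       double size_radius = -1.0) {
  const int nv = V.nrow(), nf = Fm.nrow();
  double cen[3] = {0.0, 0.0, 0.0};
  if (center.size() == 3) {
    for (int d = 0; d < 3; ++d) cen[d] = center[d];
  } else {
    for (int v = 0; v < nv; ++v)
      for (int d = 0; d < 3; ++d) cen[d] += V(v, d);
    for (int d = 0; d < 3; ++d) cen[d] /= nv;
  }
  const double margin_vox = cutoff + 1.0;
  const double avail = (double)(N - 1) - 2.0 * margin_vox;
  if (avail <= 0) stop("grid size N too small for the requested cutoff margin");
  double rmax2 = 0.0;
  for (int v = 0; v < nv; ++v) {
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      const double dd = V(v, d) - cen[d];
      r2 += dd * dd;
    }
    if (r2 > rmax2) rmax2 = r2;
  }
  double ext = 2.0 * std::max(std::sqrt(rmax2), size_radius);
  if (ext <= 0.0) ext = 1e-6;
  const double spacing = ext / avail;
  double origin[3];
  for (int d = 0; d < 3; ++d)
    origin[d] = cen[d] - spacing * (N - 1) * 0.5;

  const double cut = cutoff * spacing, cut2 = cut * cut;
  std::vector<double> mind2((size_t)N * N * N, 1e30);
  for (int f = 0; f < nf; ++f) {
    double tv[3][3];
    for (int v = 0; v < 3; ++v)
      for (int d = 0; d < 3; ++d) tv[v][d] = V(Fm(f, v) - 1, d);
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      double tlo = std::min(tv[0][d], std::min(tv[1][d], tv[2][d])) - cut;
      double thi = std::max(tv[0][d], std::max(tv[1][d], tv[2][d])) + cut;
      i0[d] = std::max(0, (int)std::floor((tlo - origin[d]) / spacing));
      i1[d] = std::min(N - 1, (int)std::ceil((thi - origin[d]) / spacing));
    }
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j) {
        size_t base = (size_t)N * (j + (size_t)N * k);
        for (int i = i0[0]; i <= i1[0]; ++i) {
          double p[3] = {origin[0] + i * spacing, origin[1] + j * spacing,
                         origin[2] + k * spacing};
          const double d2 = pt_tri_dist2(p, tv[0], tv[1], tv[2]);
          if (d2 < mind2[base + i]) mind2[base + i] = d2;
        }
      }
  }
  IntegerVector occ((R_xlen_t)N * N * N);
  for (size_t v = 0; v < mind2.size(); ++v) occ[v] = mind2[v] < cut2 ? 1 : 0;
  return List::create(Named("data") = occ,
                      Named("origin") = NumericVector::create(origin[0], origin[1], origin[2]),
                      Named("spacing") = spacing,
                      Named("outer_radius") = ext * 0.5 + cut);
}
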