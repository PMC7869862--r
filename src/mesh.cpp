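#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra: each grid cell (8 voxel centers)
// is split into 6 tetrahedra sharing the main diagonal; within a tetrahedron
// the isosurface is one or two planar triangles with vertices linearly
// interpolated along edges. Only the total area is needed, so no mesh
// topology is kept. Coordinates are scaled by the physical voxel spacing.
// Layout: linear = z + nz*(y + ny*x); field must be padded so the surface
// closes (callers pad with background).

struct P3 { double z, y, x; };

static inline P3 interp(const P3& a, const P3& b, double va, double vb,
                        double iso) {
  const double t = (iso - va) / (vb - va);
  P3 r;
  r.z = a.z + t * (b.z - a.z);
  r.y = a.y + t * (b.y - a.y);
  r.x = a.x + t * (b.x - a.x);
  return r;
}

static inline double tri_area(const P3& a, const P3& b, const P3& c) {
  const double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
  const double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
  const double cz = uy * vx - ux * vy;
  const double cy = ux * vz - uz * vx;
  const double cx = uz * vy - uy * vz;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

static double tet_area(const P3 p[4], const double v[4], double iso) {
  bool above[4];
  int na = 0;
  for (int i = 0; i < 4; ++i) { above[i] = v[i] >= iso; if (above[i]) ++na; }
  if (na == 0 || na == 4) return 0.0;
  int in[4], out[4], ni = 0, no = 0;
  for (int i = 0; i < 4; ++i) (above[i] ? in[ni++] : out[no++]) = i;
  if (na == 1 || na == 3) {
    const int s = (na == 1) ? in[0] : out[0];
    const int* o = (na == 1) ? out : in;
    P3 q[3];
    for (int i = 0; i < 3; ++i)
      q[i] = interp(p[s], p[o[i]], v[s], v[o[i]], iso);
    return tri_area(q[0], q[1], q[2]);
  }
  // 2-2 case: quad with corners on the four in-out edges
  const P3 q0 = interp(p[in[0]], p[out[0]], v[in[0]], v[out[0]], iso);
  const P3 q1 = interp(p[in[0]], p[out[1]], v[in[0]], v[out[1]], iso);
  const P3 q2 = interp(p[in[1]], p[out[1]], v[in[1]], v[out[1]], iso);
  const P3 q3 = interp(p[in[1]], p[out[0]], v[in[1]], v[out[0]], iso);
  return tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
}

// corner numbering within a cell, offsets (z, y, x)
static const int CZ[8] = { 0, 0, 0, 0, 1, 1, 1, 1 };
static const int CY[8] = { 0, 0, 1, 1, 0, 0, 1, 1 };
static const int CX[8] = { 0, 1, 1, 0, 0, 1, 1, 0 };
// 6-tetrahedra decomposition sharing diagonal 0-6
static const int TETS[6][4] = {
  { 0, 5, 1, 6 }, { 0, 1, 2, 6 }, { 0, 2, 3, 6 },
  { 0, 3, 7, 6 }, { 0, 7, 4, 6 }, { 0, 4, 5, 6 }
};

// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, IntegerVector dims,
                     NumericVector spacing, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double area = 0.0;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double v[8];
        P3 p[8];
        bool any = false, all = true;
        for (int i = 0; i < 8; ++i) {
          const int zz = z + CZ[i], yy = y + CY[i], xx = x + CX[i];
          v[i] = field[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
          p[i].z = zz * sz; p[i].y = yy * sy; p[i].x = xx * sx;
          if (v[i] >= iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4];
          double tv[4];
          for (int i = 0; i < 4; ++i) {
            tp[i] = p[TETS[t][i]];
            tv[i] = v[TETS[t][i]];
          }
          area += tet_area(tp, tv, iso);
        }
      }
  return area;
}
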