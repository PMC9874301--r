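// Triangulated isosurface area by marching tetrahedra: each grid cell is
// split into six tetrahedra around the main diagonal; intersections of the
// level set with tetrahedron edges are triangulated case by case. Vertex
// positions are linearly interpolated, so the estimator is exact for fields
// that are linear within a tetrahedron.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// corner bits: 0=x, 1=y, 2=z; six tetrahedra sharing the 0-7 diagonal
static const int TETS[6][4] = {
  {0, 5, 7, 1}, {0, 1, 7, 3}, {0, 3, 7, 2},
  {0, 2, 7, 6}, {0, 6, 7, 4}, {0, 4, 7, 5}
};

static inline void interp(const double* vx, const double* vy, const double* vz,
                          const double* f, int a, int b, double level,
                          double* px, double* py, double* pz) {
  double t = (level - f[a]) / (f[b] - f[a]);
  *px = vx[a] + t * (vx[b] - vx[a]);
  *py = vy[a] + t * (vy[b] - vy[a]);
  *pz = vz[a] + t * (vz[b] - vz[a]);
}

static inline double tri_area(double ax, double ay, double az, double bx,
                              double by, double bz, double cx, double cy,
                              double cz) {
  double ux = bx - ax, uy = by - ay, uz = bz - az;
  double vx = cx - ax, vy = cy - ay, vz = cz - az;
  double wx = uy * vz - uz * vy;
  double wy = uz * vx - ux * vz;
  double wz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(wx * wx + wy * wy + wz * wz);
}

// Total area (in units of spacing^2) of the isosurface {field = level};
// "inside" is field > level. No triangles are emitted outside the grid, so a
// structure running through a domain face is left open there.
// [[Rcpp::export]]
double mt_area_cpp(NumericVector field, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  double area = 0.0;
  double f[8], vx[8], vy[8], vz[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          f[c] = field[ci + (R_xlen_t)nx * cj + nxy * ck];
          vx[c] = ci; vy[c] = cj; vz[c] = ck;
        }
        // quick reject: all corners on one side
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) (f[c] > level ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in[4], ni = 0, out[4], no = 0;
          for (int c = 0; c < 4; ++c) {
            if (f[T[c]] > level) in[ni++] = T[c];
            else out[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          double ax, ay, az, bx, by, bz, cx, cy, cz, dx, dy, dz;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? in[0] : out[0];
            const int* oth = (ni == 1) ? out : in;
            interp(vx, vy, vz, f, apex, oth[0], level, &ax, &ay, &az);
            interp(vx, vy, vz, f, apex, oth[1], level, &bx, &by, &bz);
            interp(vx, vy, vz, f, apex, oth[2], level, &cx, &cy, &cz);
            area += tri_area(ax, ay, az, bx, by, bz, cx, cy, cz);
          } else {
            // quad: edges A-C, A-D, B-D, B-C (A,B inside; C,D outside)
            interp(vx, vy, vz, f, in[0], out[0], level, &ax, &ay, &az);
            interp(vx, vy, vz, f, in[0], out[1], level, &bx, &by, &bz);
            interp(vx, vy, vz, f, in[1], out[1], level, &cx, &cy, &cz);
            interp(vx, vy, vz, f, in[1], out[0], level, &dx, &dy, &dz);
            area += tri_area(ax, ay, az, bx, by, bz, cx, cy, cz);
            area += tri_area(ax, ay, az, cx, cy, cz, dx, dy, dz);
          }
        }
      }
  return area;
}
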