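// Mean intercept length sampling: for each test direction a bundle of
// parallel lines is marched through the volume; bone path length and the
// number of background-to-bone crossings are accumulated per direction.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// directions: n x 3 unit vectors; lines enter through the grid face most
// orthogonal to the direction, spaced line_spacing voxels apart, sampled with
// nearest-neighbor lookup at the given step (voxels). Returns per-direction
// bone length (voxel units) and intercept counts.
// [[Rcpp::export]]
NumericMatrix mil_cpp(LogicalVector mask, IntegerVector dim,
                      NumericMatrix directions, double line_spacing,
                      double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const int nd = directions.nrow();
  NumericMatrix out(nd, 2);

  for (int d = 0; d < nd; ++d) {
    double wx = directions(d, 0), wy = directions(d, 1), wz = directions(d, 2);
    double aw[3] = {std::fabs(wx), std::fabs(wy), std::fabs(wz)};
    int axis = 0;
    if (aw[1] > aw[0]) axis = 1;
    if (aw[2] > aw[axis]) axis = 2;

    // two axes spanning the entry face
    int u_axis = (axis + 1) % 3, v_axis = (axis + 2) % 3;
    int nu = (u_axis == 0 ? nx : (u_axis == 1 ? ny : nz));
    int nv = (v_axis == 0 ? nx : (v_axis == 1 ? ny : nz));
    int nax = (axis == 0 ? nx : (axis == 1 ? ny : nz));
    double w_ax = (axis == 0 ? wx : (axis == 1 ? wy : wz));
    double tmax = (double)nax / std::fabs(w_ax); // path length to traverse

    double bone_len = 0.0;
    double crossings = 0.0;

    for (double u0 = 0.5; u0 < nu; u0 += line_spacing)
      for (double v0 = 0.5; v0 < nv; v0 += line_spacing) {
        double p[3];
        p[u_axis] = u0;
        p[v_axis] = v0;
        p[axis] = (w_ax > 0) ? 0.0 : (double)nax - 1e-9;
        int prev = 0; // outside counts as background
        int nsamp = (int)(tmax / step);
        double px = p[0], py = p[1], pz = p[2];
        double sx = wx * step, sy = wy * step, sz = wz * step;
        for (int s = 0; s < nsamp; ++s) {
          int ix = (int)px, iy = (int)py, iz = (int)pz;
          int cur = 0;
          if (ix >= 0 && iy >= 0 && iz >= 0 && ix < nx && iy < ny && iz < nz)
            cur = mask[ix + (R_xlen_t)nx * iy + nxy * iz] ? 1 : 0;
          if (cur) bone_len += step;
          if (cur && !prev) crossings += 1.0;
          prev = cur;
          px += sx; py += sy; pz += sz;
        }
      }
    out(d, 0) = bone_len;
    out(d, 1) = crossings;
  }
  return out;
}
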