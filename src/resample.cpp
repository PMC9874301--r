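// Resampling of a volume under a rigid map. For each output voxel the world
// position x is mapped to y = R (x - c) + c + t in the input volume's frame
// and the input is interpolated there (nearest, trilinear, or Lanczos-3
// windowed sinc). Out-of-domain samples take the background value.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int LANCZOS_A = 3;
static const int LUT_N = 4096;
static std::vector<double> lanczos_lut;

static void init_lut() {
  if (!lanczos_lut.empty()) return;
  lanczos_lut.resize(LUT_N + 2);
  for (int i = 0; i <= LUT_N + 1; ++i) {
    double x = (double)i * LANCZOS_A / LUT_N;
    double v;
    if (x < 1e-8) v = 1.0;
    else if (x >= LANCZOS_A) v = 0.0;
    else {
      double px = M_PI * x;
      v = LANCZOS_A * std::sin(px) * std::sin(px / LANCZOS_A) / (px * px);
    }
    lanczos_lut[i] = v;
  }
}

static inline double lanczos_w(double x) {
  x = std::fabs(x);
  if (x >= LANCZOS_A) return 0.0;
  double u = x * LUT_N / LANCZOS_A;
  int i = (int)u;
  double fr = u - i;
  return lanczos_lut[i] * (1.0 - fr) + lanczos_lut[i + 1] * fr;
}

// [[Rcpp::export]]
NumericVector rigid_resample_cpp(NumericVector vol, IntegerVector dim,
                                 double spacing, NumericVector origin,
                                 NumericMatrix rot, NumericVector center,
                                 NumericVector trans, IntegerVector out_dim,
                                 double out_spacing, NumericVector out_origin,
                                 int method, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  init_lut();

  const double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  const double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  const double r20 = rot(2, 0), r21 = rot(2, 1), r22 = rot(2, 2);

  R_xlen_t o = 0;
  for (int k = 0; k < mz; ++k) {
    double xz = out_origin[2] + k * out_spacing - center[2];
    for (int j = 0; j < my; ++j) {
      double xy = out_origin[1] + j * out_spacing - center[1];
      for (int i = 0; i < mx; ++i, ++o) {
        double xx = out_origin[0] + i * out_spacing - center[0];
        double yx = r00 * xx + r01 * xy + r02 * xz + center[0] + trans[0];
        double yy = r10 * xx + r11 * xy + r12 * xz + center[1] + trans[1];
        double yz = r20 * xx + r21 * xy + r22 * xz + center[2] + trans[2];
        // continuous voxel index in the input grid
        double ci = (yx - origin[0]) / spacing;
        double cj = (yy - origin[1]) / spacing;
        double ck = (yz - origin[2]) / spacing;

        double val = background;
        if (method == 0) { // nearest
          int ii = (int)std::lround(ci), jj = (int)std::lround(cj),
              kk = (int)std::lround(ck);
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            val = vol[ii + (R_xlen_t)nx * jj + nxy * kk];
        } else if (method == 1) { // trilinear
          // clamp exact-edge samples into the last cell
          int i0 = std::min((int)std::floor(ci), nx - 2);
          int j0 = std::min((int)std::floor(cj), ny - 2);
          int k0 = std::min((int)std::floor(ck), nz - 2);
          if (i0 >= 0 && j0 >= 0 && k0 >= 0 && ci <= nx - 1 + 1e-9 &&
              cj <= ny - 1 + 1e-9 && ck <= nz - 1 + 1e-9) {
            double fx = ci - i0, fy = cj - j0, fz = ck - k0;
            R_xlen_t b = i0 + (R_xlen_t)nx * j0 + nxy * k0;
            double c00 = vol[b] * (1 - fx) + vol[b + 1] * fx;
            double c10 = vol[b + nx] * (1 - fx) + vol[b + nx + 1] * fx;
            double c01 = vol[b + nxy] * (1 - fx) + vol[b + nxy + 1] * fx;
            double c11 =
                vol[b + nxy + nx] * (1 - fx) + vol[b + nxy + nx + 1] * fx;
            double c0 = c00 * (1 - fy) + c10 * fy;
            double c1 = c01 * (1 - fy) + c11 * fy;
            val = c0 * (1 - fz) + c1 * fz;
          }
        } else { // Lanczos-3
          int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj),
              k0 = (int)std::floor(ck);
          if (i0 - 2 >= 0 && j0 - 2 >= 0 && k0 - 2 >= 0 && i0 + 3 < nx &&
              j0 + 3 < ny && k0 + 3 < nz) {
            double wxv[6], wyv[6], wzv[6];
            double swx = 0, swy = 0, swz = 0;
            for (int m = 0; m < 6; ++m) {
              wxv[m] = lanczos_w(ci - (i0 - 2 + m));
              wyv[m] = lanczos_w(cj - (j0 - 2 + m));
              wzv[m] = lanczos_w(ck - (k0 - 2 + m));
              swx += wxv[m]; swy += wyv[m]; swz += wzv[m];
            }
            double acc = 0.0;
            for (int mk = 0; mk < 6; ++mk) {
              double accj = 0.0;
              R_xlen_t bk = nxy * (k0 - 2 + mk);
              for (int mj = 0; mj < 6; ++mj) {
                R_xlen_t bj = bk + (R_xlen_t)nx * (j0 - 2 + mj) + (i0 - 2);
                double acci = 0.0;
                for (int mi = 0; mi < 6; ++mi) acci += wxv[mi] * vol[bj + mi];
                accj += wyv[mj] * acci;
              }
              acc += wzv[mk] * accj;
            }
            val = acc / (swx * swy * swz);
          } else if (ci >= -1e-9 && cj >= -1e-9 && ck >= -1e-9 &&
                     ci <= nx - 1 + 1e-9 && cj <= ny - 1 + 1e-9 &&
                     ck <= nz - 1 + 1e-9) {
            // near the border fall back to trilinear (edge-clamped)
            i0 = std::max(0, std::min(i0, nx - 2));
            j0 = std::max(0, std::min(j0, ny - 2));
            k0 = std::max(0, std::min(k0, nz - 2));
            double fx = ci - i0, fy = cj - j0, fz = ck - k0;
            R_xlen_t b = i0 + (R_xlen_t)nx * j0 + nxy * k0;
            double c00 = vol[b] * (1 - fx) + vol[b + 1] * fx;
            double c10 = vol[b + nx] * (1 - fx) + vol[b + nx + 1] * fx;
            double c01 = vol[b + nxy] * (1 - fx) + vol[b + nxy + 1] * fx;
            double c11 =
                vol[b + nxy + nx] * (1 - fx) + vol[b + nxy + nx + 1] * fx;
            double c0 = c00 * (1 - fy) + c10 * fy;
            double c1 = c01 * (1 - fy) + c11 * fy;
            val = c0 * (1 - fz) + c1 * fz;
          }
        }
        out[o] = val;
      }
    }
  }
  return out;
}
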