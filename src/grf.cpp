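// Spectral Gaussian random field evaluation for the trabecular foam phantom.
// The field is a randomized cosine expansion f(x) = sqrt(2/K) sum_f
// cos(k_f . x + phi_f); with frequencies drawn from the spectral measure of a
// squared-exponential covariance this converges to a stationary Gaussian
// field with unit variance. Evaluation along grid lines uses the angle-
// addition recurrence so the inner loop is trigonometry-free.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Field values at arbitrary points (n x 3, world um).
// [[Rcpp::export]]
NumericVector grf_points_cpp(NumericMatrix pts, NumericMatrix freqs,
                             NumericVector phases) {
  const int n = pts.nrow(), K = freqs.nrow();
  const double amp = std::sqrt(2.0 / K);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int f = 0; f < K; ++f)
      s += std::cos(freqs(f, 0) * x + freqs(f, 1) * y + freqs(f, 2) * z +
                    phases[f]);
    out[i] = amp * s;
  }
  return out;
}

// Per-voxel membership fraction of the thresholded foam {f > tau} restricted
// to the z-window [zlo, zhi), computed by supersampling each voxel with an
// ss^3 subgrid. Grid is isotropic with the given spacing and world origin at
// the center of voxel (0,0,0).
// [[Rcpp::export]]
NumericVector grf_fraction_cpp(IntegerVector dim, NumericVector origin,
                               double spacing, int ss, NumericMatrix freqs,
                               NumericVector phases, double tau, double zlo,
                               double zhi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int K = freqs.nrow();
  const double amp = std::sqrt(2.0 / K);
  NumericVector out(n);

  std::vector<double> kx(K), ky(K), kz(K), ph(K), cd(K), sd(K);
  for (int f = 0; f < K; ++f) {
    kx[f] = freqs(f, 0); ky[f] = freqs(f, 1); kz[f] = freqs(f, 2);
    ph[f] = phases[f];
    cd[f] = std::cos(kx[f] * spacing); // per-voxel step along x
    sd[f] = std::sin(kx[f] * spacing);
  }
  std::vector<double> cc(K), sscur(K);

  // subsample offsets inside one voxel, centered on the voxel center
  std::vector<double> offs(ss);
  for (int m = 0; m < ss; ++m) offs[m] = ((m + 0.5) / ss - 0.5) * spacing;
  const double inv_total = 1.0 / ((double)ss * ss * ss);

  for (int mz = 0; mz < ss; ++mz)
    for (int my = 0; my < ss; ++my)
      for (int mx2 = 0; mx2 < ss; ++mx2) {
        double ox = origin[0] + offs[mx2];
        for (int k = 0; k < nz; ++k) {
          double z = origin[2] + k * spacing + offs[mz];
          bool zin = (z >= zlo && z < zhi);
          R_xlen_t basek = (R_xlen_t)nx * ny * k;
          for (int j = 0; j < ny; ++j) {
            R_xlen_t base = basek + (R_xlen_t)nx * j;
            if (!zin) continue;
            double y = origin[1] + j * spacing + offs[my];
            for (int f = 0; f < K; ++f) {
              double th = kx[f] * ox + ky[f] * y + kz[f] * z + ph[f];
              cc[f] = std::cos(th);
              sscur[f] = std::sin(th);
            }
            for (int i = 0; i < nx; ++i) {
              double s = 0.0;
              for (int f = 0; f < K; ++f) s += cc[f];
              if (amp * s > tau) out[base + i] += inv_total;
              for (int f = 0; f < K; ++f) {
                double c2 = cc[f] * cd[f] - sscur[f] * sd[f];
                sscur[f] = sscur[f] * cd[f] + cc[f] * sd[f];
                cc[f] = c2;
              }
            }
          }
        }
      }
  return out;
}
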