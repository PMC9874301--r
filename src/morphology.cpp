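// 3D binary-image primitives: exact Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower-envelope algorithm), maximal-inscribed-
// sphere local thickness, and connected-component labeling.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double BM_INF = 1e20;

// 1D squared distance transform of sampled function f (length n).
static void dt1d(const double* f, double* d, int* v, double* z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BM_INF;
  z[1] = BM_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BM_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the nearest
// voxel where mask is FALSE. Voxels where mask is FALSE get 0.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BM_INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + nxy * k];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz);
      for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
    }
  return out;
}

// Hildebrand-Ruegsegger local thickness in voxel units: thickness at a voxel
// is the diameter of the largest sphere fully contained in the structure that
// covers it. Sphere radii come from the EDT (distance to nearest background
// voxel center); redundant sphere centers are pruned by the sound neighbor
// criterion r(q) >= r(p) + |p - q| before painting.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector d2 = edt_sq_cpp(mask, dim);
  NumericVector out(n);

  std::vector<double> r(n);
  for (R_xlen_t i = 0; i < n; ++i) r[i] = mask[i] ? std::sqrt(d2[i]) : 0.0;

  // collect non-redundant sphere centers (distance ridge)
  std::vector<R_xlen_t> centers;
  centers.reserve(1024);
  const double eps = 1e-9;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = i + (R_xlen_t)nx * j + nxy * k;
        if (!mask[p]) continue;
        double rp = r[p];
        bool dominated = false;
        for (int dk = -1; dk <= 1 && !dominated; ++dk)
          for (int dj = -1; dj <= 1 && !dominated; ++dj)
            for (int di = -1; di <= 1 && !dominated; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              R_xlen_t q = ii + (R_xlen_t)nx * jj + nxy * kk;
              if (!mask[q]) continue;
              double dist = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (r[q] >= rp + dist - eps) dominated = true;
            }
        if (!dominated) centers.push_back(p);
      }

  // paint largest spheres first; skip spheres already fully superseded
  std::sort(centers.begin(), centers.end(),
            [&](R_xlen_t a, R_xlen_t b) { return r[a] > r[b]; });
  for (R_xlen_t ci = 0; ci < (R_xlen_t)centers.size(); ++ci) {
    R_xlen_t p = centers[ci];
    double rp = r[p];
    double diam = 2.0 * rp;
    int pk = (int)(p / nxy);
    int pj = (int)((p - (R_xlen_t)pk * nxy) / nx);
    int pi = (int)(p - (R_xlen_t)pk * nxy - (R_xlen_t)pj * nx);
    // a sphere also covers voxels whose center lies within half a voxel of
    // its boundary (the voxel straddles the continuous sphere)
    double rc = rp + 0.5;
    int ir = (int)std::floor(rc + eps);
    double r2 = rc * rc + eps;
    for (int dk = -ir; dk <= ir; ++dk) {
      int kk = pk + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        int jj = pj + dj;
        if (jj < 0 || jj >= ny) continue;
        double zz = (double)(dk * dk + dj * dj);
        if (zz > r2) continue;
        int irx = (int)std::floor(std::sqrt(r2 - zz));
        int ilo = std::max(pi - irx, 0), ihi = std::min(pi + irx, nx - 1);
        R_xlen_t base = (R_xlen_t)nx * jj + nxy * kk;
        for (int ii = ilo; ii <= ihi; ++ii) {
          R_xlen_t q = base + ii;
          if (mask[q] && out[q] < diam) out[q] = diam;
        }
      }
    }
  }
  return out;
}

// Connected-component labeling (6- or 26-connectivity) by explicit-stack
// flood fill. Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n);

  std::vector<int> offs_di, offs_dj, offs_dk;
  if (connectivity == 6) {
    int di[] = {1, -1, 0, 0, 0, 0};
    int dj[] = {0, 0, 1, -1, 0, 0};
    int dk[] = {0, 0, 0, 0, 1, -1};
    offs_di.assign(di, di + 6);
    offs_dj.assign(dj, dj + 6);
    offs_dk.assign(dk, dk + 6);
  } else if (connectivity == 26) {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          offs_di.push_back(di);
          offs_dj.push_back(dj);
          offs_dk.push_back(dk);
        }
  } else {
    stop("connectivity must be 6 or 26");
  }
  const int nn = (int)offs_di.size();

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int pk = (int)(p / nxy);
      int pj = (int)((p - (R_xlen_t)pk * nxy) / nx);
      int pi = (int)(p - (R_xlen_t)pk * nxy - (R_xlen_t)pj * nx);
      for (int m = 0; m < nn; ++m) {
        int ii = pi + offs_di[m], jj = pj + offs_dj[m], kk = pk + offs_dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * jj + nxy * kk;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}
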