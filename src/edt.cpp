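// Exact 3D squared Euclidean distance transform (separable lower-envelope
// algorithm of Felzenszwalb & Huttenlocher). With unit spacing and integer
// inputs all squared distances are exact integers held in doubles.

#include "core.h"

using namespace Rcpp;

// 1D squared distance transform along a sampled line with spacing s.
// f holds squared distances in, d gets squared distances out.
static void dt1d(const double* f, double* d, int n, double s2,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == R_PosInf) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = R_NegInf; z[1] = R_PosInf;
      continue;
    }
    double sint = 0.0;
    while (k >= 0) {
      int p = v[k];
      sint = ((f[q] + (double)q * q * s2) - (f[p] + (double)p * p * s2)) /
             (2.0 * s2 * (double)(q - p));
      if (sint <= z[k]) k--; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = R_NegInf; z[1] = R_PosInf;
    } else {
      ++k; v[k] = q; z[k] = sint; z[k + 1] = R_PosInf;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = R_PosInf;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    double dq = (double)(q - v[j]);
    d[q] = dq * dq * s2 + f[v[j]];
  }
}

void dist_to_set_sq(const int* set, const int nz, const int ny, const int nx,
                    const double sz, const double sy, const double sx,
                    const bool border_in_set, std::vector<double>& d2) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  d2.assign(n, R_PosInf);
  for (R_xlen_t i = 0; i < n; ++i) if (set[i]) d2[i] = 0.0;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along z (contiguous)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double* line = &d2[(R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      std::copy(line, line + nz, f.begin());
      dt1d(f.data(), d.data(), nz, sz * sz, v, z);
      std::copy(d.begin(), d.begin() + nz, line);
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = d2[base + (R_xlen_t)nz * y];
      dt1d(f.data(), d.data(), ny, sy * sy, v, z);
      for (int y = 0; y < ny; ++y) d2[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = d2[base + (R_xlen_t)nz * ny * x];
      dt1d(f.data(), d.data(), nx, sx * sx, v, z);
      for (int x = 0; x < nx; ++x) d2[base + (R_xlen_t)nz * ny * x] = d[x];
    }

  if (border_in_set) {
    // nearest virtual set voxel beyond a face lies at the perpendicular foot
    for (int x = 0; x < nx; ++x) {
      double dx2 = std::min((double)(x + 1) * sx, (double)(nx - x) * sx);
      dx2 *= dx2;
      for (int y = 0; y < ny; ++y) {
        double dy2 = std::min((double)(y + 1) * sy, (double)(ny - y) * sy);
        dy2 *= dy2;
        double dmin = std::min(dx2, dy2);
        R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int zz = 0; zz < nz; ++zz) {
          double dz2 = std::min((double)(zz + 1) * sz, (double)(nz - zz) * sz);
          dz2 *= dz2;
          double m = std::min(dmin, dz2);
          if (m < d2[base + zz]) d2[base + zz] = m;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector dist_to_set_sq_cpp(LogicalVector set, IntegerVector dim,
                                 NumericVector spacing, bool border_in_set) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> d2;
  dist_to_set_sq(LOGICAL(set), nz, ny, nx,
                 spacing[0], spacing[1], spacing[2], border_in_set, d2);
  NumericVector out(d2.size());
  std::copy(d2.begin(), d2.end(), out.begin());
  return out;
}
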