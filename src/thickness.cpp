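// Local thickness by largest inscribed sphere: every object voxel receives
// the radius of the largest sphere that fits in the object and contains it.
// Spheres are open balls on voxel-center distances; the candidate radius at a
// center c is the Euclidean distance from c to the nearest background voxel
// center (field outside the volume counts as background).
//
// Algorithm: exact distance transform, then a distance-ridge reduction that
// removes every center whose ball is contained in a 26-neighbour's ball
// (containment: d(c,c') + r(c) <= r(c')), then sphere painting from the
// surviving centers in order of decreasing radius. The reduction is
// conservative, so painted values equal the exhaustive search exactly; with
// isotropic spacing all comparisons are carried out in integer arithmetic.

#include "core.h"
#include <algorithm>

using namespace Rcpp;

// ball(c, sqrt(a)) contained in ball(c', sqrt(cc)) at squared offset b:
// sqrt(a) + sqrt(b) <= sqrt(cc). Integer-exact form for isotropic grids.
static inline bool contained_int(double a, double b, double cc) {
  double rhs = cc - a - b;
  if (rhs < 0) return false;
  return 4.0 * a * b <= rhs * rhs;
}

static inline bool contained_float(double a, double b, double cc) {
  return std::sqrt(a) + std::sqrt(b) + 1e-9 <= std::sqrt(cc);
}

// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector object, IntegerVector dim,
                                  NumericVector spacing,
                                  bool border_background) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const bool iso = (sz == sy && sy == sx);
  // work in voxel units when isotropic so squared distances are integers
  const double uz = iso ? 1.0 : sz, uy = iso ? 1.0 : sy, ux = iso ? 1.0 : sx;
  const double scale = iso ? sz : 1.0;

  // distance to background, squared, in work units
  std::vector<int> bg(n);
  const int* obj = LOGICAL(object);
  for (R_xlen_t i = 0; i < n; ++i) bg[i] = obj[i] ? 0 : 1;
  std::vector<double> d2;
  dist_to_set_sq(bg.data(), nz, ny, nx, uz, uy, ux, border_background, d2);
  // no background anywhere (possible with border as object): cap radii at
  // the volume diagonal so sphere painting stays bounded
  const double cap = (double)nz * nz * uz * uz + (double)ny * ny * uy * uy +
                     (double)nx * nx * ux * ux;
  for (R_xlen_t i = 0; i < n; ++i) if (d2[i] > cap) d2[i] = cap;

  // distance-ridge reduction over 26-neighbourhoods
  std::vector<R_xlen_t> cand;
  cand.reserve(1024);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int zz = 0; zz < nz; ++zz) {
        R_xlen_t i = zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!obj[i]) continue;
        double a = d2[i];
        bool redundant = false;
        for (int dx = -1; dx <= 1 && !redundant; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1 && !redundant; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int zn = zz + dz; if (zn < 0 || zn >= nz) continue;
              R_xlen_t j = zn + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (!obj[j]) continue;
              double b = (double)(dz * dz) * uz * uz +
                         (double)(dy * dy) * uy * uy +
                         (double)(dx * dx) * ux * ux;
              bool cont = iso ? contained_int(a, b, d2[j])
                              : contained_float(a, b, d2[j]);
              if (cont) { redundant = true; break; }
            }
          }
        }
        if (!redundant) cand.push_back(i);
      }

  std::sort(cand.begin(), cand.end(),
            [&d2](R_xlen_t a, R_xlen_t b) { return d2[a] > d2[b]; });

  std::vector<double> out(n, 0.0);
  const R_xlen_t strideY = nz, strideX = (R_xlen_t)nz * ny;
  for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ++ci) {
    R_xlen_t c = cand[ci];
    double r2 = d2[c];
    double r = std::sqrt(r2);
    int cx = (int)(c / strideX);
    int cy = (int)((c - (R_xlen_t)cx * strideX) / strideY);
    int cz = (int)(c - (R_xlen_t)cx * strideX - (R_xlen_t)cy * strideY);
    int rz = (int)(r / uz), ry = (int)(r / uy), rx = (int)(r / ux);
    int z0 = std::max(0, cz - rz), z1 = std::min(nz - 1, cz + rz);
    int y0 = std::max(0, cy - ry), y1 = std::min(ny - 1, cy + ry);
    int x0 = std::max(0, cx - rx), x1 = std::min(nx - 1, cx + rx);
    for (int x = x0; x <= x1; ++x) {
      double ddx = (double)(x - cx) * ux; ddx *= ddx;
      if (ddx >= r2) continue;
      for (int y = y0; y <= y1; ++y) {
        double ddy = (double)(y - cy) * uy; ddy *= ddy;
        if (ddx + ddy >= r2) continue;
        R_xlen_t base = (R_xlen_t)x * strideX + (R_xlen_t)y * strideY;
        for (int zv = z0; zv <= z1; ++zv) {
          R_xlen_t i = base + zv;
          if (!obj[i] || out[i] >= r2) continue;
          double ddz = (double)(zv - cz) * uz; ddz *= ddz;
          if (ddx + ddy + ddz < r2) out[i] = r2;
        }
      }
    }
  }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = obj[i] ? std::sqrt(out[i]) * scale : NA_REAL;
  return res;
}
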