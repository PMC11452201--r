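// Rasterization of capsules (tubes around polyline centerlines) and balls
// into a logical volume. Voxels are set where the normalized point-to-segment
// distance is strictly below 1 (open tube, consistent with the open-ball
// thickness convention). The target mask is updated in place; callers own it.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
int rasterize_polyline_cpp(LogicalVector mask, Nullable<LogicalVector> region,
                           IntegerVector dim, NumericMatrix pts,
                           NumericVector radius_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  int* m = LOGICAL(mask);
  const int* reg = region.isNull() ? nullptr : LOGICAL(region.get());
  const double rz = radius_vox[0], ry = radius_vox[1], rx = radius_vox[2];
  const R_xlen_t strideY = nz, strideX = (R_xlen_t)nz * ny;
  int newly = 0;

  const int nseg = pts.nrow() - 1;
  for (int s = 0; s < std::max(nseg, 1); ++s) {
    // endpoints in radius-scaled coordinates (z,y,x)
    int s1 = (nseg >= 1) ? s + 1 : s;
    double az = pts(s, 0) / rz, ay = pts(s, 1) / ry, ax = pts(s, 2) / rx;
    double bz = pts(s1, 0) / rz, by = pts(s1, 1) / ry, bx = pts(s1, 2) / rx;
    double dz = bz - az, dy = by - ay, dx = bx - ax;
    double dd = dz * dz + dy * dy + dx * dx;

    int z0 = (int)std::floor(std::min(pts(s, 0), pts(s1, 0)) - rz);
    int z1 = (int)std::ceil(std::max(pts(s, 0), pts(s1, 0)) + rz);
    int y0 = (int)std::floor(std::min(pts(s, 1), pts(s1, 1)) - ry);
    int y1 = (int)std::ceil(std::max(pts(s, 1), pts(s1, 1)) + ry);
    int x0 = (int)std::floor(std::min(pts(s, 2), pts(s1, 2)) - rx);
    int x1 = (int)std::ceil(std::max(pts(s, 2), pts(s1, 2)) + rx);
    z0 = std::max(z0, 0); z1 = std::min(z1, nz - 1);
    y0 = std::max(y0, 0); y1 = std::min(y1, ny - 1);
    x0 = std::max(x0, 0); x1 = std::min(x1, nx - 1);

    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int zv = z0; zv <= z1; ++zv) {
          double qz = (double)zv / rz - az;
          double qy = (double)y / ry - ay;
          double qx = (double)x / rx - ax;
          double t = 0.0;
          if (dd > 0) {
            t = (qz * dz + qy * dy + qx * dx) / dd;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double ez = qz - t * dz, ey = qy - t * dy, ex = qx - t * dx;
          if (ez * ez + ey * ey + ex * ex < 1.0) {
            R_xlen_t i = zv + (R_xlen_t)y * strideY + (R_xlen_t)x * strideX;
            if (reg && !reg[i]) continue;
            if (!m[i]) { m[i] = 1; ++newly; }
          }
        }
  }
  return newly;
}
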