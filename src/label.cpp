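// 3D connected-component labelling (6- or 26-connectivity), iterative BFS.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int* m = LOGICAL(mask);
  IntegerVector lab(n, 0);
  int* L = INTEGER(lab);

  std::vector<int> offz, offy, offx;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offz.push_back(dz); offy.push_back(dy); offx.push_back(dx);
      }
  const int nb = (int)offz.size();

  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!m[i] || L[i]) continue;
    ++cur;
    L[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int px = (int)(p / ((R_xlen_t)nz * ny));
      int py = (int)((p / nz) % ny);
      int pz = (int)(p % nz);
      for (int k = 0; k < nb; ++k) {
        int zz = pz + offz[k], yy = py + offy[k], xx = px + offx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (m[q] && !L[q]) { L[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}
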