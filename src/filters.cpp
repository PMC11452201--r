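// Separable convolution along one axis, zero padding, "same" output size.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int klen = kernel.size();
  const int half = klen / 2;
  NumericVector out(n);
  const double* v = REAL(vol);
  double* o = REAL(out);
  const double* k = REAL(kernel);

  const R_xlen_t strideY = nz, strideX = (R_xlen_t)nz * ny;
  int len; R_xlen_t stride;
  if (axis == 1) { len = nz; stride = 1; }
  else if (axis == 2) { len = ny; stride = strideY; }
  else { len = nx; stride = strideX; }

  std::vector<double> line(len);
  // iterate over all lines along `axis`
  int d1, d2; R_xlen_t s1, s2;
  if (axis == 1) { d1 = ny; s1 = strideY; d2 = nx; s2 = strideX; }
  else if (axis == 2) { d1 = nz; s1 = 1; d2 = nx; s2 = strideX; }
  else { d1 = nz; s1 = 1; d2 = ny; s2 = strideY; }

  for (int b = 0; b < d2; ++b)
    for (int a = 0; a < d1; ++a) {
      R_xlen_t base = (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
      for (int i = 0; i < len; ++i) line[i] = v[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        int j0 = std::max(0, i - half), j1 = std::min(len - 1, i + half);
        for (int j = j0; j <= j1; ++j) acc += line[j] * k[half + (i - j)];
        o[base + (R_xlen_t)i * stride] = acc;
      }
    }
  return out;
}
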