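// Separable 1D convolution along an axis of a dense 3D array stored in R's
// column-major layout, with replicate (clamp) boundary handling. The kernel
// must have odd length and is applied centred. Loops are ordered so the inner
// accumulation runs over the contiguous first dimension wherever possible.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_conv3_axis(NumericVector a, IntegerVector dim,
                             NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int K = kernel.size();
  if (K % 2 == 0) stop("kernel length must be odd");
  const int hw = K / 2;
  if ((R_xlen_t)nx * ny * nz != a.size()) stop("dim does not match array length");
  NumericVector out(a.size());
  const double *src = a.begin();
  double *dst = out.begin();
  const double *w = kernel.begin();

  if (axis == 1) { // along x: contiguous runs of length nx
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        const double *col = src + (R_xlen_t)(z * ny + y) * nx;
        double *ocol = dst + (R_xlen_t)(z * ny + y) * nx;
        int lo = hw < nx ? hw : nx;
        int hi = nx - hw > lo ? nx - hw : lo;
        for (int x = 0; x < lo; ++x) { // left boundary, clamped
          double acc = 0;
          for (int k = 0; k < K; ++k) {
            int xi = x + k - hw;
            if (xi < 0) xi = 0;
            else if (xi >= nx) xi = nx - 1;
            acc += w[k] * col[xi];
          }
          ocol[x] = acc;
        }
        for (int x = lo; x < hi; ++x) { // interior, branch-free
          double acc = 0;
          const double *c = col + x - hw;
          for (int k = 0; k < K; ++k) acc += w[k] * c[k];
          ocol[x] = acc;
        }
        for (int x = hi; x < nx; ++x) { // right boundary, clamped
          double acc = 0;
          for (int k = 0; k < K; ++k) {
            int xi = x + k - hw;
            if (xi < 0) xi = 0;
            else if (xi >= nx) xi = nx - 1;
            acc += w[k] * col[xi];
          }
          ocol[x] = acc;
        }
      }
    }
  } else if (axis == 2) { // along y: axpy over contiguous x-rows
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        double *orow = dst + ((R_xlen_t)z * ny + y) * nx;
        for (int x = 0; x < nx; ++x) orow[x] = 0;
        for (int k = 0; k < K; ++k) {
          int yi = y + k - hw;
          if (yi < 0) yi = 0;
          else if (yi >= ny) yi = ny - 1;
          const double *irow = src + ((R_xlen_t)z * ny + yi) * nx;
          const double wk = w[k];
          for (int x = 0; x < nx; ++x) orow[x] += wk * irow[x];
        }
      }
    }
  } else if (axis == 3) { // along z: axpy over contiguous xy-planes
    const R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int z = 0; z < nz; ++z) {
      double *oplane = dst + z * plane;
      for (R_xlen_t p = 0; p < plane; ++p) oplane[p] = 0;
      for (int k = 0; k < K; ++k) {
        int zi = z + k - hw;
        if (zi < 0) zi = 0;
        else if (zi >= nz) zi = nz - 1;
        const double *iplane = src + zi * plane;
        const double wk = w[k];
        for (R_xlen_t p = 0; p < plane; ++p) oplane[p] += wk * iplane[p];
      }
    }
  } else {
    stop("axis must be 1, 2 or 3");
  }
  out.attr("dim") = dim;
  return out;
}
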