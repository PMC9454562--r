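#include <Rcpp.h>
using namespace Rcpp;

// Feature maps live as C x V matrices over an (n1,n2,n3) voxel grid with
// column-major voxel linearisation v = i1 + n1*(i2 + n2*i3) (0-based here;
// the R side is 1-based). These two kernels are the only hot loops of the
// conv-net engine; all matrix products go through BLAS on the R side.
// Padding-boundary checks are hoisted out of the inner loops by clipping
// the kernel index ranges per output coordinate.

static inline void clip_range(const int o, const int stride, const int pad,
                              const int n, const int k, int& lo, int& hi) {
  // valid kernel offsets kk with 0 <= o*stride - pad + kk < n
  const int base = o * stride - pad;
  lo = base < 0 ? -base : 0;
  hi = (n - 1 - base < k - 1) ? n - 1 - base : k - 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, const IntegerVector& dims,
                      const int k, const int stride, const int pad) {
  const int C  = x.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if (x.ncol() != n1 * n2 * n3)
    stop("im2col3: feature matrix does not match voxel grid");
  const int o1 = (n1 + 2 * pad - k) / stride + 1;
  const int o2 = (n2 + 2 * pad - k) / stride + 1;
  const int o3 = (n3 + 2 * pad - k) / stride + 1;
  if (o1 < 1 || o2 < 1 || o3 < 1)
    stop("im2col3: kernel larger than padded input");
  const int kk = k * k * k;
  const int CK = C * kk;
  NumericMatrix col(CK, o1 * o2 * o3);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int oz = 0; oz < o3; ++oz) {
    int kzlo, kzhi; clip_range(oz, stride, pad, n3, k, kzlo, kzhi);
    for (int oy = 0; oy < o2; ++oy) {
      int kylo, kyhi; clip_range(oy, stride, pad, n2, k, kylo, kyhi);
      for (int ox = 0; ox < o1; ++ox) {
        int kxlo, kxhi; clip_range(ox, stride, pad, n1, k, kxlo, kxhi);
        const int ix0 = ox * stride - pad;
        double* colj = cp + (size_t)(ox + o1 * (oy + (size_t)o2 * oz)) * CK;
        for (int c = 0; c < C; ++c) {
          const int rbase_c = c * kk;
          for (int kz = kzlo; kz <= kzhi; ++kz) {
            const int iz = oz * stride - pad + kz;
            for (int ky = kylo; ky <= kyhi; ++ky) {
              const int iy = oy * stride - pad + ky;
              const long long vbase = (long long)ix0 +
                (long long)n1 * (iy + (long long)n2 * iz);
              double* dst = colj + rbase_c + kz * k * k + ky * k;
              const double* src = xp + c + (size_t)C * vbase;
              for (int kx = kxlo; kx <= kxhi; ++kx)
                dst[kx] = src[(size_t)C * kx];
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col3: scatter-add patch columns back onto the voxel grid.
// `indims` is the grid being reconstructed; the column grid is the conv
// output grid implied by (indims, k, stride, pad).
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& col, const IntegerVector& indims,
                      const int C, const int k, const int stride,
                      const int pad) {
  const int n1 = indims[0], n2 = indims[1], n3 = indims[2];
  const int o1 = (n1 + 2 * pad - k) / stride + 1;
  const int o2 = (n2 + 2 * pad - k) / stride + 1;
  const int o3 = (n3 + 2 * pad - k) / stride + 1;
  const int kk = k * k * k;
  const int CK = C * kk;
  if (col.nrow() != CK || col.ncol() != o1 * o2 * o3)
    stop("col2im3: column matrix does not match geometry");
  NumericMatrix x(C, n1 * n2 * n3);
  const double* cp = col.begin();
  double* xp = x.begin();
  for (int oz = 0; oz < o3; ++oz) {
    int kzlo, kzhi; clip_range(oz, stride, pad, n3, k, kzlo, kzhi);
    for (int oy = 0; oy < o2; ++oy) {
      int kylo, kyhi; clip_range(oy, stride, pad, n2, k, kylo, kyhi);
      for (int ox = 0; ox < o1; ++ox) {
        int kxlo, kxhi; clip_range(ox, stride, pad, n1, k, kxlo, kxhi);
        const int ix0 = ox * stride - pad;
        const double* colj = cp + (size_t)(ox + o1 * (oy + (size_t)o2 * oz)) * CK;
        for (int c = 0; c < C; ++c) {
          const int rbase_c = c * kk;
          for (int kz = kzlo; kz <= kzhi; ++kz) {
            const int iz = oz * stride - pad + kz;
            for (int ky = kylo; ky <= kyhi; ++ky) {
              const int iy = oy * stride - pad + ky;
              const long long vbase = (long long)ix0 +
                (long long)n1 * (iy + (long long)n2 * iz);
              const double* src = colj + rbase_c + kz * k * k + ky * k;
              double* dst = xp + c + (size_t)C * vbase;
              for (int kx = kxlo; kx <= kxhi; ++kx)
                dst[(size_t)C * kx] += src[kx];
            }
          }
        }
      }
    }
  }
  return x;
}
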