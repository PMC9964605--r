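#include <Rcpp.h>
using namespace Rcpp;

// 2x2-kernel, stride-1 im2col with optional right/bottom zero padding.
// x has dim (N, Cin, H, W) in R's column-major layout. The returned patch
// matrix has one row per (n, out_row, out_col) -- n fastest -- and one
// column per (offset, channel), offsets ordered (0,0),(1,0),(0,1),(1,1)
// to match the weight-matrix row blocks used on the R side.
static const int DI[4] = {0, 1, 0, 1};
static const int DJ[4] = {0, 0, 1, 1};

// [[Rcpp::export]]
NumericMatrix im2col_k2_cpp(NumericVector x, IntegerVector pad) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  const int oh = H + pad[0] - 1, ow = W + pad[1] - 1;
  NumericMatrix cols((R_xlen_t)N * oh * ow, 4 * C);
  const double *xp = x.begin();
  double *cp0 = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)N * oh * ow;
  for (int o = 0; o < 4; ++o) {
    for (int c = 0; c < C; ++c) {
      double *col = cp0 + nrow * ((R_xlen_t)o * C + c);
      for (int j = 0; j < ow; ++j) {
        const int sj = j + DJ[o];
        if (sj >= W) continue;  // zero padding: leave column entries at 0
        for (int i = 0; i < oh; ++i) {
          const int si = i + DI[o];
          if (si >= H) continue;
          const double *src = xp + (R_xlen_t)N * (c + (R_xlen_t)C * (si + (R_xlen_t)H * sj));
          double *dst = col + (R_xlen_t)N * (i + (R_xlen_t)oh * j);
          for (int n = 0; n < N; ++n) dst[n] = src[n];
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_k2_cpp: scatter patch-matrix gradients back onto the
// (N, Cin, H, W) input, dropping contributions that fell in the padding.
// [[Rcpp::export]]
NumericVector col2im_k2_cpp(NumericMatrix dcols, IntegerVector dims,
                            IntegerVector pad) {
  const int N = dims[0], C = dims[1], H = dims[2], W = dims[3];
  const int oh = H + pad[0] - 1, ow = W + pad[1] - 1;
  NumericVector dx((R_xlen_t)N * C * H * W);
  dx.attr("dim") = dims;
  const double *cp0 = dcols.begin();
  double *dp = dx.begin();
  const R_xlen_t nrow = (R_xlen_t)N * oh * ow;
  for (int o = 0; o < 4; ++o) {
    for (int c = 0; c < C; ++c) {
      const double *col = cp0 + nrow * ((R_xlen_t)o * C + c);
      for (int j = 0; j < ow; ++j) {
        const int sj = j + DJ[o];
        if (sj >= W) continue;
        for (int i = 0; i < oh; ++i) {
          const int si = i + DI[o];
          if (si >= H) continue;
          const double *src = col + (R_xlen_t)N * (i + (R_xlen_t)oh * j);
          double *dst = dp + (R_xlen_t)N * (c + (R_xlen_t)C * (si + (R_xlen_t)H * sj));
          for (int n = 0; n < N; ++n) dst[n] += src[n];
        }
      }
    }
  }
  return dx;
}
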