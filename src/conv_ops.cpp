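#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (H*W*N) x C matrices with row index r = h + H*(w-1) +
// H*W*(n-1) (1-based). These kernels implement zero-padded 3x3 im2col and
// its adjoint; column j of a patch block is ordered j = dh_i + 3*(dw_i-1)
// to match matrix(weights, 9*Cin, Cout) on an array of dim (3,3,Cin,Cout).

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& F, int H, int W, int N) {
  const int C = F.ncol();
  const int rows = H * W * N;
  NumericMatrix M(rows, 9 * C);
  const double* f = REAL(F);
  double* m = REAL(M);
  for (int c = 0; c < C; ++c) {
    const double* fc = f + (R_xlen_t)c * rows;
    int j = 0;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh, ++j) {
        double* mc = m + ((R_xlen_t)(j + 9 * c)) * rows;
        for (int n = 0; n < N; ++n) {
          const int nb = n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw;
            double* out = mc + nb + w * H;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) out[h] = 0.0;
              continue;
            }
            const double* in = fc + nb + ws * H;
            const int h0 = (dh < 0) ? 1 : 0;
            const int h1 = (dh > 0) ? H - 1 : H;
            if (dh < 0) out[0] = 0.0;
            if (dh > 0) out[H - 1] = 0.0;
            for (int h = h0; h < h1; ++h) out[h] = in[h + dh];
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& dM, int H, int W, int N,
                          int C) {
  const int rows = H * W * N;
  NumericMatrix dF(rows, C);
  const double* m = REAL(dM);
  double* f = REAL(dF);
  for (int c = 0; c < C; ++c) {
    double* fc = f + (R_xlen_t)c * rows;
    int j = 0;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh, ++j) {
        const double* mc = m + ((R_xlen_t)(j + 9 * c)) * rows;
        for (int n = 0; n < N; ++n) {
          const int nb = n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw;
            if (ws < 0 || ws >= W) continue;
            const double* in = mc + nb + w * H;
            double* out = fc + nb + ws * H;
            const int h0 = (dh < 0) ? 1 : 0;
            const int h1 = (dh > 0) ? H - 1 : H;
            for (int h = h0; h < h1; ++h) out[h + dh] += in[h];
          }
        }
      }
    }
  }
  return dF;
}
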