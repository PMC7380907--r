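// Low-level kernels for the E-GONet convolutional classifier: im2col /
// col2im for 3x3 same-padded convolutions and 2x2 max-pooling, on arrays
// laid out (H, W, C, N) column-major as in R. The matrix products
// themselves stay in R (BLAS).
#include <Rcpp.h>
using namespace Rcpp;

// col matrix: rows ordered (i fastest, then j, then n), columns
// (k-1)*Cin + c with k = (dj-1)*3 + di over the 3x3 window.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int Cin, int N) {
  const int HW = H * W, rows = HW * N;
  NumericMatrix col(rows, 9 * Cin);
  const double *px = x.begin();
  for (int k = 0; k < 9; ++k) {
    const int dj = k / 3, di = k % 3; // offsets -1..1 via (d-1)
    for (int c = 0; c < Cin; ++c) {
      double *pc = &col(0, k * Cin + c);
      for (int n = 0; n < N; ++n) {
        const double *pn = px + (size_t)n * HW * Cin + (size_t)c * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - 1;
          double *dst = pc + (size_t)n * HW + (size_t)j * H;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) dst[i] = 0.0;
          } else {
            const double *src = pn + (size_t)jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + di - 1;
              dst[i] = (ii < 0 || ii >= H) ? 0.0 : src[ii];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int H, int W, int Cin, int N) {
  const int HW = H * W;
  NumericVector dx((size_t)HW * Cin * N);
  double *px = dx.begin();
  for (int k = 0; k < 9; ++k) {
    const int dj = k / 3, di = k % 3;
    for (int c = 0; c < Cin; ++c) {
      const double *pc = &dcol(0, k * Cin + c);
      for (int n = 0; n < N; ++n) {
        double *pn = px + (size_t)n * HW * Cin + (size_t)c * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - 1;
          if (jj < 0 || jj >= W) continue;
          const double *src = pc + (size_t)n * HW + (size_t)j * H;
          double *dst = pn + (size_t)jj * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - 1;
            if (ii >= 0 && ii < H) dst[ii] += src[i];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  return dx;
}

// 2x2 max-pool, stride 2, floor semantics. Returns the pooled array and
// the linear argmax (1-based, into x) per output cell; ties break to the
// first element in (row, column) scan order.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  const double *px = x.begin();
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)n * H * W * C + (size_t)c * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++t) {
          size_t i0 = base + (size_t)(2 * j) * H + 2 * i;
          size_t cand[4] = {i0, i0 + 1, i0 + (size_t)H, i0 + (size_t)H + 1};
          size_t best = cand[0];
          double bv = px[cand[0]];
          for (int q = 1; q < 4; ++q)
            if (px[cand[q]] > bv) { bv = px[cand[q]]; best = cand[q]; }
          out[t] = bv;
          arg[t] = (int)best + 1;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              int H, int W, int C, int N) {
  NumericVector dx((size_t)H * W * C * N);
  const R_xlen_t m = dout.size();
  for (R_xlen_t t = 0; t < m; ++t) dx[argmax[t] - 1] += dout[t];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Swap the last two dimensions of an (H, W, A, B) array.
// [[Rcpp::export]]
NumericVector cpp_swap34(NumericVector x, int H, int W, int A, int B) {
  NumericVector out((size_t)H * W * A * B);
  const size_t HW = (size_t)H * W;
  const double *px = x.begin();
  double *po = out.begin();
  for (int b = 0; b < B; ++b)
    for (int a = 0; a < A; ++a) {
      const double *src = px + (b * (size_t)A + a) * HW;
      double *dst = po + (a * (size_t)B + b) * HW;
      for (size_t t = 0; t < HW; ++t) dst[t] = src[t];
    }
  out.attr("dim") = IntegerVector::create(H, W, B, A);
  return out;
}
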