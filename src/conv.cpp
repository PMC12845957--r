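// Batched 2-D convolution (stride 1, "same" padding) via im2col + BLAS gemm.
// Activations use layout (H, W, N, C); kernels (kh, kw, cin, cout).
// The batch is processed in chunks to bound the im2col buffer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int CHUNK = 32;

// Fill the im2col buffer for images [n0, n1) of x: one row per output pixel
// (h, w, n), one column per kernel tap (i, j, ci); out-of-range taps are 0.
static void im2col_fill(const double* x, int H, int W, int N, int C,
                        int kh, int kw, int pt, int pl,
                        int n0, int n1, arma::mat& im) {
  const int nch = n1 - n0;
  const long m = (long)H * W * nch;
  im.zeros(m, (long)kh * kw * C);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (long)ci * H * W * N;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* col = im.colptr(i + kh * (j + kw * ci));
        for (int n = n0; n < n1; ++n) {
          const double* xn = xc + (long)n * H * W;
          double* coln = col + (long)(n - n0) * H * W;
          for (int w0 = 0; w0 < W; ++w0) {
            int ws = w0 + j - pl;
            if (ws < 0 || ws >= W) continue;
            const double* xcol = xn + (long)ws * H;
            double* dst = coln + (long)w0 * H;
            int hlo = std::max(0, pt - i);          // h with hs >= 0
            int hhi = std::min(H, H + pt - i);      // h with hs < H
            for (int h = hlo; h < hhi; ++h) dst[h] = xcol[h + i - pt];
          }
        }
      }
    }
  }
}

// kernel reshaped to (kh*kw*cin) x cout matching im2col column order
static arma::mat kernel_matrix(const double* w, int kh, int kw, int cin, int cout) {
  arma::mat wm((long)kh * kw * cin, cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          wm(i + kh * (j + kw * ci), co) =
            w[i + (long)kh * (j + kw * ((long)ci + (long)cin * co))];
  return wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cin = wdim[2], cout = wdim[3];
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  if (cin != C) stop("channel mismatch");
  NumericVector out((R_xlen_t)H * W * N * cout);
  out.attr("dim") = IntegerVector::create(H, W, N, cout);
  arma::mat wm = kernel_matrix(w.begin(), kh, kw, cin, cout);
  arma::mat im;
  for (int n0 = 0; n0 < N; n0 += CHUNK) {
    const int n1 = std::min(N, n0 + CHUNK);
    im2col_fill(x.begin(), H, W, N, C, kh, kw, pt, pl, n0, n1, im);
    arma::mat y = im * wm; // (H*W*nch) x cout
    y.each_row() += arma::rowvec(bias.begin(), cout);
    const int nch = n1 - n0;
    for (int co = 0; co < cout; ++co) {
      const double* src = y.colptr(co);
      double* dst = out.begin() + (long)co * H * W * N + (long)n0 * H * W;
      std::copy(src, src + (long)H * W * nch, dst);
    }
  }
  return out;
}

// Returns list(dx, dw, db) for dz = gradient at the (pre-activation) output.
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dz, bool compute_dx = true) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cin = wdim[2], cout = wdim[3];
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  arma::mat wm = kernel_matrix(w.begin(), kh, kw, cin, cout);
  arma::mat dwm((long)kh * kw * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * W * N * C);
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  arma::mat im;
  for (int n0 = 0; n0 < N; n0 += CHUNK) {
    const int n1 = std::min(N, n0 + CHUNK);
    const int nch = n1 - n0;
    const long m = (long)H * W * nch;
    // gather dz chunk as (H*W*nch) x cout
    arma::mat dzm(m, cout);
    for (int co = 0; co < cout; ++co) {
      const double* src = dz.begin() + (long)co * H * W * N + (long)n0 * H * W;
      std::copy(src, src + m, dzm.colptr(co));
    }
    im2col_fill(x.begin(), H, W, N, C, kh, kw, pt, pl, n0, n1, im);
    dwm += im.t() * dzm;
    db += arma::sum(dzm, 0).t();
    if (!compute_dx) continue;
    // dx chunk: col2im of dzm * wm'
    arma::mat dim_ = dzm * wm.t(); // m x (kh*kw*cin)
    for (int ci = 0; ci < C; ++ci) {
      double* dxc = dx.begin() + (long)ci * H * W * N;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const double* col = dim_.colptr(i + kh * (j + kw * ci));
          for (int n = n0; n < n1; ++n) {
            double* dxn = dxc + (long)n * H * W;
            const double* coln = col + (long)(n - n0) * H * W;
            for (int w0 = 0; w0 < W; ++w0) {
              int ws = w0 + j - pl;
              if (ws < 0 || ws >= W) continue;
              double* dxcol = dxn + (long)ws * H;
              const double* src = coln + (long)w0 * H;
              int hlo = std::max(0, pt - i);
              int hhi = std::min(H, H + pt - i);
              for (int h = hlo; h < hhi; ++h) dxcol[h + i - pt] += src[h];
            }
          }
        }
      }
    }
  }
  NumericVector dwv((R_xlen_t)kh * kw * cin * cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          dwv[i + (long)kh * (j + kw * ((long)ci + (long)cin * co))] =
            dwm(i + kh * (j + kw * ci), co);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
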