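// Minimal dense conv-net primitives: im2col convolution forward/backward and
// max pooling with argmax caching. Activations are 4-D column-major arrays
// [H, W, C, N]; weights are [kh, kw, Cin, Cout]. All loops are single-thread
// deterministic; matrix products go through BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  arma::mat out(Ho * (arma::uword)Wo, (arma::uword)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo * stride - pad + j;
          for (int ho = 0; ho < Ho; ++ho) {
            int hs = ho * stride - pad + i;
            double v = 0.0;
            if (hs >= 0 && hs < H && ws >= 0 && ws < W)
              v = xc[hs + (size_t)H * ws];
            out(ho + (arma::uword)Ho * wo, col) = v;
          }
        }
      }
    }
  }
  return out;
}

static void col2im_add(const arma::mat& cols, double* dx, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo * stride - pad + j;
          if (ws < 0 || ws >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hs = ho * stride - pad + i;
            if (hs < 0 || hs >= H) continue;
            xc[hs + (size_t)H * ws] += cols(ho + (arma::uword)Ho * wo, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * C, Cout,
               false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X = im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
                         kh, kw, stride, pad, Ho, Wo);
    arma::mat Y = X * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * C, Cout,
               false, true);
  arma::mat dWm((arma::uword)kh * kw * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    arma::mat X = im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
                         kh, kw, stride, pad, Ho, Wo);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (arma::uword)Ho * Wo, Cout, false, true);
    dWm += X.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dXcol = dY * Wm.t();
    col2im_add(dXcol, dx.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pad, Ho, Wo);
  }
  NumericVector dwOut(w.size());
  dwOut.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dwOut.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwOut,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List nn_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)Ho * Wo * C * n;
    int* in = idx.begin() + (size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int bestIdx = -1;
          for (int j = 0; j < k; ++j) {
            int ws = wo * stride - pad + j;
            if (ws < 0 || ws >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hs = ho * stride - pad + i;
              if (hs < 0 || hs >= H) continue;
              double v = xc[hs + (size_t)H * ws];
              if (v > best) { best = v; bestIdx = hs + H * (ws + W * c); }
            }
          }
          size_t o = ho + (size_t)Ho * (wo + (size_t)Wo * c);
          yn[o] = (bestIdx < 0) ? 0.0 : best;
          in[o] = bestIdx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bw(NumericVector dy, IntegerVector idx,
                            IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  size_t per = (size_t)dy.size() / N;
  for (int n = 0; n < N; ++n) {
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    const double* dyn = dy.begin() + per * n;
    const int* in = idx.begin() + per * n;
    for (size_t o = 0; o < per; ++o)
      if (in[o] >= 0) dxn[in[o]] += dyn[o];
  }
  return dx;
}
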