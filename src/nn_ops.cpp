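// Low-level tensor primitives for the package's neural networks.
// Layout convention follows R arrays (column-major): activations are
// (H, W, C, N), convolution kernels are (kh, kw, Cin, Cout).
//
// Samples are gathered with im2col and multiplied in grouped GEMMs (one
// BLAS call per group of samples) for throughput; group size is capped by
// a fixed memory budget.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Receptive fields of one sample into columns `col0 .. col0+Ho*Wo-1` of
// `cols`. Row index is i + kh*(j + kw*c), matching the kernel reshape.
// Loops are ordered so writes walk down each column sequentially.
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat &cols, size_t col0) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *dst = cols.colptr(col0 + ho + (size_t)Ho * wo);
      for (int c = 0; c < C; ++c) {
        const double *xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int win = wo * stride + j - pad;
          const double *xcol = xc + (size_t)H * win;
          for (int i = 0; i < kh; ++i) {
            int hin = ho * stride + i - pad;
            *dst++ = (win < 0 || win >= W || hin < 0 || hin >= H)
                         ? 0.0 : xcol[hin];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &cols, size_t col0, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double *dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *src = cols.colptr(col0 + ho + (size_t)Ho * wo);
      for (int c = 0; c < C; ++c) {
        double *xc = dx + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int win = wo * stride + j - pad;
          double *xcol = xc + (size_t)H * win;
          for (int i = 0; i < kh; ++i) {
            int hin = ho * stride + i - pad;
            if (win >= 0 && win < W && hin >= 0 && hin < H)
              xcol[hin] += *src;
            ++src;
          }
        }
      }
    }
  }
}

// samples per GEMM group under a ~64 MB scratch budget
static int group_size(int rows, int colsPerSample, int N) {
  double budget = 8.0e6;  // doubles
  int g = (int)(budget / ((double)rows * colsPerSample));
  if (g < 1) g = 1;
  if (g > N) g = N;
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cw = wd[2], F = wd[3];
  if (Cw != C) stop("kernel/input channel mismatch");
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("convolution output would be empty");
  int rows = kh * kw * C, P = Ho * Wo;

  arma::mat Wmat(const_cast<double *>(w.begin()), rows, F, false, true);
  NumericVector out((size_t)P * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);

  int g = group_size(rows, P, N);
  arma::mat cols(rows, (size_t)P * g);
  for (int n0 = 0; n0 < N; n0 += g) {
    int gn = std::min(g, N - n0);
    for (int n = 0; n < gn; ++n)
      im2col(x.begin() + (size_t)H * W * C * (n0 + n), H, W, C, kh, kw,
             stride, pad, Ho, Wo, cols, (size_t)P * n);
    arma::mat o = Wmat.t() * cols.cols(0, (size_t)P * gn - 1); // F x P*gn
    double *op = out.begin() + (size_t)P * F * n0;
    for (int n = 0; n < gn; ++n)
      for (int f = 0; f < F; ++f) {
        const double *src = o.colptr((size_t)P * n);
        double bf = b[f];
        double *dst = op + (size_t)P * (f + (size_t)F * n);
        for (int p = 0; p < P; ++p) dst[p] = src[p * F + f] + bf;
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dout,
                  int stride, int pad, bool wantDx = true,
                  bool wantDw = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  int rows = kh * kw * C, P = Ho * Wo;

  arma::mat Wmat(const_cast<double *>(w.begin()), rows, F, false, true);
  NumericVector dx(wantDx ? (size_t)H * W * C * N : 0);
  if (wantDx) dx.attr("dim") = xd;
  NumericVector dw((size_t)rows * F);
  dw.attr("dim") = wd;
  NumericVector db(F);
  arma::mat dWacc(rows, F, arma::fill::zeros);

  int g = group_size(rows, P, N);
  arma::mat cols(rows, (size_t)P * g);
  for (int n0 = 0; n0 < N; n0 += g) {
    int gn = std::min(g, N - n0);
    // dout of the group as (P*gn) x F with per-sample blocks
    arma::mat Dn((size_t)P * gn, F);
    for (int n = 0; n < gn; ++n) {
      const double *dp = dout.begin() + (size_t)P * F * (n0 + n);
      for (int f = 0; f < F; ++f) {
        double s = 0.0;
        double *dst = Dn.colptr(f) + (size_t)P * n;
        const double *src = dp + (size_t)P * f;
        for (int p = 0; p < P; ++p) { dst[p] = src[p]; s += src[p]; }
        db[f] += s;
      }
    }
    if (wantDw) {
      for (int n = 0; n < gn; ++n)
        im2col(x.begin() + (size_t)H * W * C * (n0 + n), H, W, C, kh, kw,
               stride, pad, Ho, Wo, cols, (size_t)P * n);
      dWacc += cols.cols(0, (size_t)P * gn - 1) * Dn;
    }
    if (wantDx) {
      arma::mat dcols = Wmat * Dn.t();  // rows x (P*gn)
      for (int n = 0; n < gn; ++n)
        col2im(dcols, (size_t)P * n, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dx.begin() + (size_t)H * W * C * (n0 + n));
    }
  }
  std::copy(dWacc.begin(), dWacc.end(), dw.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, implemented directly as the adjoint of a
// stride-`stride` convolution: out = col2im(W * x_cols). Input (H,W,C,N)
// maps to (Ho,Wo,F,N) with Ho = stride*(H-1) + kh - 2*pad + outPad.
// Kernel layout (kh, kw, F, C): the equivalent forward conv maps F -> C.
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(NumericVector x, NumericVector w,
                            NumericVector b, int stride, int pad,
                            int outPad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[2], Cw = wd[3];
  if (Cw != C) stop("kernel/input channel mismatch");
  int Ho = stride * (H - 1) + kh - 2 * pad + outPad;
  int Wo = stride * (W - 1) + kw - 2 * pad + outPad;
  int rows = kh * kw * F, P = H * W;

  arma::mat Wmat(const_cast<double *>(w.begin()), rows, C, false, true);
  NumericVector out((size_t)Ho * Wo * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);

  for (int n = 0; n < N; ++n) {
    // x sample as (P x C)
    arma::mat Xn(P, C);
    const double *xp = x.begin() + (size_t)P * C * n;
    for (int c = 0; c < C; ++c)
      std::copy(xp + (size_t)P * c, xp + (size_t)P * (c + 1),
                Xn.colptr(c));
    arma::mat dcols = Wmat * Xn.t();  // rows x P
    double *op = out.begin() + (size_t)Ho * Wo * F * n;
    col2im(dcols, 0, Ho, Wo, F, kh, kw, stride, pad, H, W, op);
    for (int f = 0; f < F; ++f) {
      double bf = b[f];
      double *dst = op + (size_t)Ho * Wo * f;
      for (int p = 0; p < Ho * Wo; ++p) dst[p] += bf;
    }
  }
  return out;
}

// Backward of cpp_convt_fwd: dx = conv(dout, W) (stride-`stride` forward
// conv), dw from im2col(dout) * x, db = per-channel sum of dout.
// [[Rcpp::export]]
List cpp_convt_bwd(NumericVector x, NumericVector w, NumericVector dout,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[2];
  IntegerVector od = dout.attr("dim");
  int Ho = od[0], Wo = od[1];
  int rows = kh * kw * F, P = H * W;

  arma::mat Wmat(const_cast<double *>(w.begin()), rows, C, false, true);
  NumericVector dx((size_t)P * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)rows * C);
  dw.attr("dim") = wd;
  NumericVector db(F);
  arma::mat dWacc(rows, C, arma::fill::zeros);

  int g = group_size(rows, P, N);
  arma::mat cols(rows, (size_t)P * g);
  for (int n0 = 0; n0 < N; n0 += g) {
    int gn = std::min(g, N - n0);
    for (int n = 0; n < gn; ++n) {
      const double *dp = dout.begin() + (size_t)Ho * Wo * F * (n0 + n);
      im2col(dp, Ho, Wo, F, kh, kw, stride, pad, H, W, cols,
             (size_t)P * n);
      for (int f = 0; f < F; ++f) {
        const double *src = dp + (size_t)Ho * Wo * f;
        double s = 0.0;
        for (int p = 0; p < Ho * Wo; ++p) s += src[p];
        db[f] += s;
      }
    }
    arma::mat sub = cols.cols(0, (size_t)P * gn - 1);
    arma::mat o = Wmat.t() * sub;  // C x (P*gn) -> dx
    for (int n = 0; n < gn; ++n) {
      double *dst = dx.begin() + (size_t)P * C * (n0 + n);
      for (int c = 0; c < C; ++c) {
        const double *src = o.colptr((size_t)P * n);
        for (int p = 0; p < P; ++p)
          dst[p + (size_t)P * c] = src[p * C + c];
      }
    }
    // dW: cols (rows x P*gn) times x-group (P*gn x C)
    arma::mat Xg((size_t)P * gn, C);
    for (int n = 0; n < gn; ++n) {
      const double *xp = x.begin() + (size_t)P * C * (n0 + n);
      for (int c = 0; c < C; ++c)
        std::copy(xp + (size_t)P * c, xp + (size_t)P * (c + 1),
                  Xg.colptr(c) + (size_t)P * n);
    }
    dWacc += sub * Xg;
  }
  std::copy(dWacc.begin(), dWacc.end(), dw.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int size, int stride) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((size_t)Ho * Wo * C * N);  // 0-based linear index

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int j = 0; j < size; ++j) {
            for (int i = 0; i < size; ++i) {
              size_t idx = (size_t)(ho * stride + i) +
                           (size_t)H * (wo * stride + j);
              double v = xp[idx];
              if (v > best) { best = v; besti = idx; }
            }
          }
          size_t o = obase + ho + (size_t)Ho * wo;
          out[o] = best;
          arg[o] = (int)(besti + (size_t)H * W * (c + (size_t)C * n));
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              IntegerVector xdim) {
  size_t total = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// Spatial batch normalisation over (H,W,C,N): statistics per channel.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mean_, NumericVector var_, bool useBatch) {
  IntegerVector xd = x.attr("dim");
  int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  double eps = 1e-5;
  std::vector<double> m(C), v(C);
  if (useBatch) {
    for (int c = 0; c < C; ++c) { m[c] = 0.0; v[c] = 0.0; }
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double *p = x.begin() + (size_t)HW * (c + (size_t)C * n);
        double s = 0.0, s2 = 0.0;
        for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
        m[c] += s; v[c] += s2;
      }
    double cnt = (double)HW * N;
    for (int c = 0; c < C; ++c) {
      m[c] /= cnt;
      v[c] = v[c] / cnt - m[c] * m[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    for (int c = 0; c < C; ++c) { m[c] = mean_[c]; v[c] = var_[c]; }
  }
  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = xd; xhat.attr("dim") = xd;
  NumericVector mR(C), vR(C), invR(C);
  for (int c = 0; c < C; ++c) {
    mR[c] = m[c]; vR[c] = v[c]; invR[c] = 1.0 / std::sqrt(v[c] + eps);
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double *xh = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      double *o = out.begin() + (size_t)HW * (c + (size_t)C * n);
      double mc = m[c], ic = invR[c], gc = gamma[c], bc = beta[c];
      for (int i = 0; i < HW; ++i) {
        xh[i] = (p[i] - mc) * ic;
        o[i] = gc * xh[i] + bc;
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["m"] = mR,
                      _["v"] = vR, _["inv"] = invR);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dout, NumericVector xhat,
                NumericVector inv, NumericVector gamma) {
  IntegerVector xd = dout.attr("dim");
  int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  double cnt = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *d = dout.begin() + (size_t)HW * (c + (size_t)C * n);
      const double *xh = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      double sg = 0.0, sb = 0.0;
      for (int i = 0; i < HW; ++i) { sg += d[i] * xh[i]; sb += d[i]; }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  NumericVector dx(dout.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *d = dout.begin() + (size_t)HW * (c + (size_t)C * n);
      const double *xh = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      double *dxp = dx.begin() + (size_t)HW * (c + (size_t)C * n);
      double gc = gamma[c], ic = inv[c];
      double a = dgamma[c] / cnt, bmean = dbeta[c] / cnt;
      for (int i = 0; i < HW; ++i)
        dxp[i] = ic * gc * (d[i] - bmean - xh[i] * a);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
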