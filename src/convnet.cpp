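// Minimal conv-net kernels: same-padding 2-D convolution (im2col + GEMM),
// 2x2 max pooling, per-channel batch-norm passes, and bilinear affine
// warping. Tensors follow R's column-major array layout (H, W, C, N).
//
// im2col uses an (HW x k*k*C) layout so that each kernel-offset slot is a
// contiguous column filled by shifted column runs of the image, and the
// GEMM output (HW x Cout) maps directly onto the R array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fill cols (HW x k*k*C) from one image (H x W x C); column index
// r = ci*k*k + kw*k + kh holds x[h + kh - pad, w + kw - pad, ci]
static void im2col(const double* xn, int H, int W, int C, int k, int pad,
                   arma::mat& cols) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ci++) {
    const double* xc = xn + (size_t)HW * ci;
    for (int kw = 0; kw < k; kw++) {
      for (int kh = 0; kh < k; kh++) {
        double* col = cols.colptr(ci * k * k + kw * k + kh);
        const int dh = kh - pad, dw = kw - pad;
        for (int w = 0; w < W; w++) {
          double* dst = col + (size_t)H * w;
          const int win = w + dw;
          if (win < 0 || win >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * win;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0);
          for (int h = h0; h < h1; h++) dst[h] = src[h + dh];
          if (h1 < H) std::fill(dst + h1, dst + H, 0.0);
        }
      }
    }
  }
}

// scatter-add dcols (HW x k*k*C) back into dx for one image
static void col2im(const arma::mat& dcols, int H, int W, int C, int k,
                   int pad, double* dxn) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ci++) {
    double* dxc = dxn + (size_t)HW * ci;
    for (int kw = 0; kw < k; kw++) {
      for (int kh = 0; kh < k; kh++) {
        const double* col = dcols.colptr(ci * k * k + kw * k + kh);
        const int dh = kh - pad, dw = kw - pad;
        for (int w = 0; w < W; w++) {
          const int win = w + dw;
          if (win < 0 || win >= W) continue;
          double* dst = dxc + (size_t)H * win;
          const double* src = col + (size_t)H * w;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; h++) dst[h + dh] += src[h];
        }
      }
    }
  }
}

// weight array (k, k, Cin, Cout) -> matrix (k*k*Cin x Cout), row order
// matching im2col columns: r = ci*k*k + kw*k + kh
static arma::mat weight_mat(const NumericVector& w, int k, int C, int Cout) {
  arma::mat Wm(k * k * C, Cout);
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < C; ci++)
      for (int kw = 0; kw < k; kw++)
        for (int kh = 0; kh < k; kh++)
          Wm(ci * k * k + kw * k + kh, co) =
              w[kh + k * (kw + k * (ci + C * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = k / 2, HW = H * W;
  arma::mat Wm = weight_mat(w, k, C, Cout);
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat cols(HW, k * k * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; n++) {
    im2col(xp + (size_t)HW * C * n, H, W, C, k, pad, cols);
    arma::mat Y(yp + (size_t)HW * Cout * n, HW, Cout, false, true);
    Y = cols * Wm;
    for (int co = 0; co < Cout; co++) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = k / 2, HW = H * W;
  arma::mat Wm = weight_mat(w, k, C, Cout);
  arma::mat dWm(k * k * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat cols(HW, k * k * C);
  const double* xp = x.begin();
  double* dxp = dx.begin();
  double* dyp = dy.begin();
  for (int n = 0; n < N; n++) {
    arma::mat dY(dyp + (size_t)HW * Cout * n, HW, Cout, false, true);
    db += arma::sum(dY, 0).t();
    im2col(xp + (size_t)HW * C * n, H, W, C, k, pad, cols);
    dWm += cols.t() * dY;
    arma::mat dcols = dY * Wm.t();  // HW x k*k*C
    col2im(dcols, H, W, C, k, pad, dxp + (size_t)HW * C * n);
  }
  NumericVector dw((size_t)k * k * C * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < C; ci++)
      for (int kw = 0; kw < k; kw++)
        for (int kh = 0; kh < k; kh++)
          dw[kh + k * (kw + k * (ci + C * co))] =
              dWm(ci * k * k + kw * k + kh, co);
  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; co++) dbv[co] = db(co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}

// [[Rcpp::export]]
List nn_pool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (long cn = 0; cn < (long)C * N; cn++) {
    const size_t base = (size_t)H * W * cn;
    for (int w = 0; w < Wo; w++) {
      for (int h = 0; h < Ho; h++) {
        size_t best = base + (size_t)(2 * h) + (size_t)H * (2 * w);
        double bv = xp[best];
        for (int a = 0; a < 2; a++)
          for (int b = 0; b < 2; b++) {
            size_t pos = base + (size_t)(2 * h + b) + (size_t)H * (2 * w + a);
            if (xp[pos] > bv) { bv = xp[pos]; best = pos; }
          }
        yp[o] = bv;
        ip[o] = (int)best;
        o++;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_pool_bwd(NumericVector dy, IntegerVector idx,
                          IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const size_t m = dy.size();
  for (size_t j = 0; j < m; j++) dxp[ip[j]] += dyp[j];
  return dx;
}

// per-channel sums and sums of squares of an (H, W, C, N) tensor
// [[Rcpp::export]]
List nn_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector s(C), sq(C);
  const double* xp = x.begin();
  for (long n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* p = xp + HW * (c + (size_t)C * n);
      double a = 0, b = 0;
      for (size_t j = 0; j < HW; j++) { a += p[j]; b += p[j] * p[j]; }
      s[c] += a; sq[c] += b;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = sq);
}

// y = x * scale[channel] + shift[channel]
// [[Rcpp::export]]
NumericVector nn_scale_shift(NumericVector x, NumericVector scale,
                             NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (long n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t off = HW * (c + (size_t)C * n);
      const double a = scale[c], b = shift[c];
      for (size_t j = 0; j < HW; j++) yp[off + j] = xp[off + j] * a + b;
    }
  }
  return y;
}

// batch-norm backward from the pre-normalization input z and the batch
// statistics; returns dx, dgamma, dbeta in one sweep pair
// [[Rcpp::export]]
List nn_bn_bwd(NumericVector dy, NumericVector z, NumericVector mu,
               NumericVector invstd, NumericVector gamma) {
  IntegerVector xd = z.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  const double* dyp = dy.begin();
  const double* zp = z.begin();
  for (long n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t off = HW * (c + (size_t)C * n);
      const double mc = mu[c], ic = invstd[c];
      double dg = 0, db = 0;
      for (size_t j = 0; j < HW; j++) {
        const double xhat = (zp[off + j] - mc) * ic;
        dg += dyp[off + j] * xhat;
        db += dyp[off + j];
      }
      dgamma[c] += dg; dbeta[c] += db;
    }
  }
  NumericVector dx(z.size());
  dx.attr("dim") = xd;
  double* dxp = dx.begin();
  for (long n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t off = HW * (c + (size_t)C * n);
      const double mc = mu[c], ic = invstd[c], gc = gamma[c];
      const double s1 = gc * dbeta[c], s2 = gc * dgamma[c];
      for (size_t j = 0; j < HW; j++) {
        const double xhat = (zp[off + j] - mc) * ic;
        dx[off + j] = ic / m * (m * gc * dyp[off + j] - s1 - xhat * s2);
      }
    }
  }
  (void)dxp;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// in-place-style ReLU and its mask multiply: y = max(x, 0)
// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t j = 0; j < (size_t)x.size(); j++)
    yp[j] = xp[j] > 0 ? xp[j] : 0;
  return y;
}

// dx = dy where y_pre > 0 else 0
// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector dy, NumericVector pre) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* dyp = dy.begin();
  const double* pp = pre.begin();
  double* dxp = dx.begin();
  for (size_t j = 0; j < (size_t)dy.size(); j++)
    dxp[j] = pp[j] > 0 ? dyp[j] : 0;
  return dx;
}

// Bilinear warp: for output pixel (xo, yo) (1-based), sample the input at
// (m[0]*xo + m[1]*yo + m[2], m[3]*xo + m[4]*yo + m[5]); outside -> fill.
// x runs along columns, y along rows (matrix convention: img[y, x]).
// [[Rcpp::export]]
NumericMatrix warp_bilinear(NumericMatrix img, NumericVector m, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int xo = 1; xo <= W; xo++) {
    for (int yo = 1; yo <= H; yo++) {
      double xi = m[0] * xo + m[1] * yo + m[2];
      double yi = m[3] * xo + m[4] * yo + m[5];
      int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      double fx = xi - x0, fy = yi - y0;
      double v = 0.0, wsum = 0.0;
      for (int a = 0; a <= 1; a++) {
        for (int b = 0; b <= 1; b++) {
          int xx = x0 + a, yy = y0 + b;
          double wt = (a ? fx : 1 - fx) * (b ? fy : 1 - fy);
          if (wt <= 0) continue;
          if (xx >= 1 && xx <= W && yy >= 1 && yy <= H) {
            v += wt * img(yy - 1, xx - 1);
            wsum += wt;
          }
        }
      }
      out(yo - 1, xo - 1) = (wsum > 0) ? v + (1.0 - wsum) * fill : fill;
    }
  }
  return out;
}
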