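// Minimal 2-D convolution kernels (im2col + GEMM) used by the autodiff tape.
// Array layout is R column-major with dims (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// Fill the im2col matrix (R = KH*KW*Ci rows, J = Ho*Wo cols) for sample n.
static void im2col(const double* x, arma::mat& cols, arma::uword n,
                   arma::uword H, arma::uword W, arma::uword Ci,
                   arma::uword KH, arma::uword KW, int pad,
                   arma::uword Ho, arma::uword Wo) {
  for (arma::uword wo = 0; wo < Wo; ++wo) {
    for (arma::uword ho = 0; ho < Ho; ++ho) {
      arma::uword j = ho + Ho * wo;
      double* colp = cols.colptr(j);
      for (arma::uword c = 0; c < Ci; ++c) {
        for (arma::uword kw = 0; kw < KW; ++kw) {
          long wi = (long)wo + (long)kw - pad;
          for (arma::uword kh = 0; kh < KH; ++kh) {
            long hi = (long)ho + (long)kh - pad;
            arma::uword r = kh + KH * (kw + KW * c);
            if (hi >= 0 && hi < (long)H && wi >= 0 && wi < (long)W)
              colp[r] = x[idx4((arma::uword)hi, (arma::uword)wi, c, n, H, W, Ci)];
            else
              colp[r] = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  arma::uword H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  arma::uword KH = dw[0], KW = dw[1], Co = dw[3];
  if ((arma::uword)dw[2] != Ci) stop("conv2d: input channels do not match kernel");
  arma::uword Ho = H + 2 * pad - KH + 1, Wo = W + 2 * pad - KW + 1;
  arma::uword R = KH * KW * Ci, J = Ho * Wo;

  NumericVector y(Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat Wm(w.begin(), R, Co, false, true);       // (R x Co), no copy
  arma::mat cols(R, J);
  for (arma::uword n = 0; n < N; ++n) {
    im2col(x.begin(), cols, n, H, W, Ci, KH, KW, pad, Ho, Wo);
    arma::mat out(y.begin() + J * Co * n, J, Co, false, true); // (J x Co) view
    out = cols.t() * Wm;                             // y[j, co]
    for (arma::uword co = 0; co < Co; ++co) out.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dy = gy.attr("dim");
  arma::uword H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  arma::uword KH = dw[0], KW = dw[1], Co = dw[3];
  arma::uword Ho = dy[0], Wo = dy[1];
  arma::uword R = KH * KW * Ci, J = Ho * Wo;

  NumericVector gx(x.size()); gx.attr("dim") = dx;
  NumericVector gw(w.size()); gw.attr("dim") = dw;
  NumericVector gb(Co);
  arma::mat Wm(w.begin(), R, Co, false, true);
  arma::mat Gw(gw.begin(), R, Co, false, true);
  arma::mat cols(R, J);
  arma::vec Gb(gb.begin(), Co, false, true);

  for (arma::uword n = 0; n < N; ++n) {
    arma::mat Gt(gy.begin() + J * Co * n, J, Co, false, true); // (J x Co)
    // weight / bias gradients
    im2col(x.begin(), cols, n, H, W, Ci, KH, KW, pad, Ho, Wo);
    Gw += cols * Gt;
    Gb += arma::sum(Gt, 0).t();
    // input gradient: col2im of Wm * Gt'
    arma::mat colg = Wm * Gt.t();                    // (R x J)
    double* gxp = gx.begin();
    for (arma::uword wo = 0; wo < Wo; ++wo) {
      for (arma::uword ho = 0; ho < Ho; ++ho) {
        arma::uword j = ho + Ho * wo;
        const double* colp = colg.colptr(j);
        for (arma::uword c = 0; c < Ci; ++c) {
          for (arma::uword kw = 0; kw < KW; ++kw) {
            long wi = (long)wo + (long)kw - pad;
            if (wi < 0 || wi >= (long)W) continue;
            for (arma::uword kh = 0; kh < KH; ++kh) {
              long hi = (long)ho + (long)kh - pad;
              if (hi < 0 || hi >= (long)H) continue;
              gxp[idx4((arma::uword)hi, (arma::uword)wi, c, n, H, W, Ci)] +=
                colp[kh + KH * (kw + KW * c)];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax indices.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  arma::uword H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: height and width must be even");
  arma::uword Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword wo = 0; wo < Wo; ++wo)
        for (arma::uword ho = 0; ho < Ho; ++ho) {
          arma::uword best = idx4(2 * ho, 2 * wo, c, n, H, W, C);
          double bv = xp[best];
          const arma::uword cand[3] = {
            idx4(2 * ho + 1, 2 * wo, c, n, H, W, C),
            idx4(2 * ho, 2 * wo + 1, c, n, H, W, C),
            idx4(2 * ho + 1, 2 * wo + 1, c, n, H, W, C)};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          arma::uword o = idx4(ho, wo, c, n, Ho, Wo, C);
          y[o] = bv;
          idx[o] = (int)best + 1;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector dimx) {
  arma::uword sz = 1;
  for (int k = 0; k < dimx.size(); ++k) sz *= (arma::uword)dimx[k];
  NumericVector gx(sz);
  gx.attr("dim") = dimx;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}
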