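// Low-level tensor operations for the segmentation networks.
//
// Tensors are R arrays in column-major layout:
//   activations  (H, W, C, N)
//   conv kernels (kh, kw, Cin, Cout)
// Convolutions use "same" padding (asymmetric when the total padding is
// odd, extra padding at the bottom/right), so spatial output size is
// ceil(H / stride) x ceil(W / stride).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int stride) { return (n + stride - 1) / stride; }

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad_top, int pad_left,
                   int Ho, int Wo, arma::mat& col) {
  // col is (kh*kw*C) x (Ho*Wo); row index = a + kh*(b + kw*c)
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const int p = oi + Ho * oj;
      double* cp = col.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < kw; ++b) {
          const int jj = oj * stride + b - pad_left;
          for (int a = 0; a < kh; ++a) {
            const int ii = oi * stride + a - pad_top;
            const int r = a + kh * (b + kw * c);
            cp[r] = (ii >= 0 && ii < H && jj >= 0 && jj < W)
              ? x[ii + H * (jj + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad_top, int pad_left,
                   int Ho, int Wo, double* gx) {
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const int p = oi + Ho * oj;
      const double* cp = col.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < kw; ++b) {
          const int jj = oj * stride + b - pad_left;
          if (jj < 0 || jj >= W) continue;
          for (int a = 0; a < kh; ++a) {
            const int ii = oi * stride + a - pad_top;
            if (ii < 0 || ii >= H) continue;
            gx[ii + H * (jj + W * c)] += cp[a + kh * (b + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         NumericVector bias, int stride) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  const int pad_h = std::max((Ho - 1) * stride + kh - H, 0);
  const int pad_w = std::max((Wo - 1) * stride + kw - W, 0);
  const int pt = pad_h / 2, pl = pad_w / 2;
  const int K = kh * kw * C, P = Ho * Wo;

  NumericVector y(static_cast<R_xlen_t>(P) * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat col(K, P);
  const bool has_bias = bias.size() > 0;

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pt, pl, Ho, Wo, col);
    arma::mat Y(y.begin() + static_cast<R_xlen_t>(n) * P * Co, P, Co, false, true);
    Y = col.t() * Wm;
    if (has_bias)
      for (int co = 0; co < Co; ++co) Y.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xd,
                NumericVector w, IntegerVector wd,
                NumericVector gy, int stride, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  const int pad_h = std::max((Ho - 1) * stride + kh - H, 0);
  const int pad_w = std::max((Wo - 1) * stride + kw - W, 0);
  const int pt = pad_h / 2, pl = pad_w / 2;
  const int K = kh * kw * C, P = Ho * Wo;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Co : 0);

  const arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat GW(gw.begin(), K, Co, false, true);
  arma::mat col(K, P);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, pt, pl, Ho, Wo, col);
    const arma::mat G(const_cast<double*>(gy.begin()) +
                      static_cast<R_xlen_t>(n) * P * Co, P, Co, false, true);
    GW += col * G;
    arma::mat gcol = Wm * G.t();  // K x P
    col2im(gcol, H, W, C, kh, kw, stride, pt, pl, Ho, Wo,
           gx.begin() + static_cast<R_xlen_t>(n) * H * W * C);
    if (has_bias)
      for (int co = 0; co < Co; ++co) gb[co] += arma::accu(G.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution with a 2x2 kernel and stride 2 (exact x2
// upsampling, no padding). Kernel layout (2, 2, Cin, Cout).

// [[Rcpp::export(name = ".tconv2_fwd")]]
NumericVector tconv2_fwd(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         NumericVector bias) {
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const bool has_bias = bias.size() > 0;

  arma::mat Wab(Ci, Co);
  for (int a = 0; a < 2; ++a) {
    for (int b = 0; b < 2; ++b) {
      for (int ci = 0; ci < Ci; ++ci)
        for (int co = 0; co < Co; ++co)
          Wab(ci, co) = w[a + 2 * (b + 2 * (ci + Ci * co))];
      for (int n = 0; n < N; ++n) {
        const arma::mat X(const_cast<double*>(x.begin()) +
                          static_cast<R_xlen_t>(n) * H * W * Ci,
                          H * W, Ci, false, true);
        arma::mat Yab = X * Wab;  // (H*W) x Co
        double* yn = y.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Co;
        for (int co = 0; co < Co; ++co) {
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yn[(2 * i + a) + Ho * ((2 * j + b) + Wo * co)] +=
                Yab(i + H * j, co);
        }
      }
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n) {
      double* yn = y.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Co;
      for (int co = 0; co < Co; ++co) {
        double* yc = yn + static_cast<R_xlen_t>(Ho) * Wo * co;
        for (int p = 0; p < Ho * Wo; ++p) yc[p] += bias[co];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv2_bwd")]]
List tconv2_bwd(NumericVector x, IntegerVector xd,
                NumericVector w, IntegerVector wd,
                NumericVector gy, bool has_bias) {
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Co : 0);

  arma::mat Wab(Ci, Co), Gab(H * W, Co);
  for (int a = 0; a < 2; ++a) {
    for (int b = 0; b < 2; ++b) {
      for (int ci = 0; ci < Ci; ++ci)
        for (int co = 0; co < Co; ++co)
          Wab(ci, co) = w[a + 2 * (b + 2 * (ci + Ci * co))];
      arma::mat GWab(Ci, Co, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        const double* gyn = gy.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Co;
        for (int co = 0; co < Co; ++co)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              Gab(i + H * j, co) =
                gyn[(2 * i + a) + Ho * ((2 * j + b) + Wo * co)];
        const arma::mat X(const_cast<double*>(x.begin()) +
                          static_cast<R_xlen_t>(n) * H * W * Ci,
                          H * W, Ci, false, true);
        arma::mat GX(gx.begin() + static_cast<R_xlen_t>(n) * H * W * Ci,
                     H * W, Ci, false, true);
        GX += Gab * Wab.t();
        GWab += X.t() * Gab;
      }
      for (int ci = 0; ci < Ci; ++ci)
        for (int co = 0; co < Co; ++co)
          gw[a + 2 * (b + 2 * (ci + Ci * co))] = GWab(ci, co);
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n) {
      const double* gyn = gy.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Co;
      for (int co = 0; co < Co; ++co) {
        const double* gc = gyn + static_cast<R_xlen_t>(Ho) * Wo * co;
        for (int p = 0; p < Ho * Wo; ++p) gb[co] += gc[p];
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2; spatial dims must be even.

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // linear index into the input sample slab
  idx.attr("dim") = y.attr("dim");

  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          int best = (2 * oi) + H * ((2 * oj) + W * c);
          double bv = xn[best];
          const int cand[3] = {
            (2 * oi + 1) + H * ((2 * oj) + W * c),
            (2 * oi) + H * ((2 * oj + 1) + W * c),
            (2 * oi + 1) + H * ((2 * oj + 1) + W * c)};
          for (int k = 0; k < 3; ++k)
            if (xn[cand[k]] > bv) { bv = xn[cand[k]]; best = cand[k]; }
          y[q] = bv;
          idx[q] = best;
          ++q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx,
                           IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xd;
  const R_xlen_t slab = static_cast<R_xlen_t>(H) * W * C;
  const R_xlen_t per = gy.size() / N;
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    double* gxn = gx.begin() + n * slab;
    for (R_xlen_t p = 0; p < per; ++p, ++q) gxn[idx[q]] += gy[q];
  }
  return gx;
}
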