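// Batch normalization forward/backward over (H, W, C, N) arrays,
// normalizing per channel across spatial positions and samples.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, IntegerVector xd, NumericVector gamma,
            NumericVector beta, double eps, bool training,
            NumericVector rmean, NumericVector rvar) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const R_xlen_t slab = static_cast<R_xlen_t>(HW) * C;
  NumericVector mu(C), v(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
        for (int i = 0; i < HW; ++i) s += p[i];
      }
      mu[c] = s / (static_cast<double>(HW) * N);
    }
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
        for (int i = 0; i < HW; ++i) {
          const double d = p[i] - mu[c];
          s += d * d;
        }
      }
      v[c] = s / (static_cast<double>(HW) * N);
    }
  } else {
    mu = clone(rmean);
    v = clone(rvar);
  }
  NumericVector sdv(C);
  for (int c = 0; c < C; ++c) sdv[c] = std::sqrt(v[c] + eps);
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      double* ph = xhat.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      double* py = y.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      const double m = mu[c], s = sdv[c], g = gamma[c], b = beta[c];
      for (int i = 0; i < HW; ++i) {
        ph[i] = (p[i] - m) / s;
        py[i] = g * ph[i] + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sdv"] = sdv,
                      _["mu"] = mu, _["v"] = v);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector gy, IntegerVector xd, NumericVector xhat,
            NumericVector sdv, NumericVector gamma) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const R_xlen_t slab = static_cast<R_xlen_t>(HW) * C;
  const double m = static_cast<double>(HW) * N;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* pg = gy.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      const double* ph = xhat.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      for (int i = 0; i < HW; ++i) {
        sg += pg[i] * ph[i];
        sb += pg[i];
      }
    }
    ggamma[c] = sg;
    gbeta[c] = sb;
  }
  NumericVector gx(gy.size());
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double t1 = gbeta[c] / m;        // mean of gxhat / gamma
    const double t2 = ggamma[c] / m;       // mean of gxhat * xhat / gamma
    const double scale = gamma[c] / sdv[c];
    for (int n = 0; n < N; ++n) {
      const double* pg = gy.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      const double* ph = xhat.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      double* px = gx.begin() + n * slab + static_cast<R_xlen_t>(c) * HW;
      for (int i = 0; i < HW; ++i)
        px[i] = scale * (pg[i] - t1 - ph[i] * t2);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
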