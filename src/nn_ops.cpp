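// Memory-bound layer primitives (batch-norm, leaky ReLU, channel concat)
// for the (H*W, C, B) activation layout.  These are single-pass loops;
// keeping them out of R avoids large intermediate allocations per step.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector rmean, NumericVector rvar,
            bool training, double eps, bool want_xhat) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0], C = d[1], B = d[2];
  const double n = (double)HW * B;
  NumericVector mu(C), v(C);
  if (training) {
    for (int b = 0; b < B; ++b) {
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + ((std::size_t)b * C + c) * HW;
        double s = 0, s2 = 0;
        for (int i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
        mu[c] += s; v[c] += s2;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] /= n;
      v[c] = std::max(v[c] / n - mu[c] * mu[c], 0.0);
    }
  } else {
    mu = clone(rmean); v = clone(rvar);
  }
  NumericVector y(Dimension(HW, C, B));
  NumericVector xhat = want_xhat ? NumericVector(Dimension(HW, C, B))
                                 : NumericVector(0);
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(v[c] + eps);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = ((std::size_t)b * C + c) * HW;
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      double* hc = want_xhat ? xhat.begin() + off : nullptr;
      const double m = mu[c], iv = inv[c], g = gamma[c], be = beta[c];
      for (int i = 0; i < HW; ++i) {
        const double h = (xc[i] - m) * iv;
        if (want_xhat) hc[i] = h;
        yc[i] = g * h + be;
      }
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("inv") = inv, Named("mean") = mu,
                      Named("var") = v);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector inv,
            NumericVector gamma) {
  IntegerVector d = dy.attr("dim");
  const int HW = d[0], C = d[1], B = d[2];
  const double n = (double)HW * B;
  NumericVector dgamma(C), dbeta(C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = ((std::size_t)b * C + c) * HW;
      const double* dc = dy.begin() + off;
      const double* hc = xhat.begin() + off;
      double s = 0, sh = 0;
      for (int i = 0; i < HW; ++i) { s += dc[i]; sh += dc[i] * hc[i]; }
      dbeta[c] += s; dgamma[c] += sh;
    }
  }
  NumericVector dx(Dimension(HW, C, B));
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = ((std::size_t)b * C + c) * HW;
      const double* dc = dy.begin() + off;
      const double* hc = xhat.begin() + off;
      double* xc = dx.begin() + off;
      const double a = gamma[c] * inv[c];
      const double mdy = dbeta[c] / n, mdyh = dgamma[c] / n;
      for (int i = 0; i < HW; ++i) {
        xc[i] = a * (dc[i] - mdy - hc[i] * mdyh);
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) {
    yi[i] = xi[i] > 0 ? xi[i] : slope * xi[i];
  }
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector dy, NumericVector x, double slope) {
  NumericVector dz(x.size());
  dz.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  const double* di = dy.begin();
  double* zi = dz.begin();
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) {
    zi[i] = xi[i] > 0 ? di[i] : slope * di[i];
  }
  return dz;
}

// [[Rcpp::export(name = ".cat_channels")]]
NumericVector cat_channels_cpp(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  const int HW = da[0], Ca = da[1], Cb = db[1], B = da[2];
  NumericVector out(Dimension(HW, Ca + Cb, B));
  const std::size_t na = (std::size_t)HW * Ca, nb = (std::size_t)HW * Cb;
  for (int i = 0; i < B; ++i) {
    std::memcpy(out.begin() + (std::size_t)i * (na + nb),
                a.begin() + (std::size_t)i * na, na * sizeof(double));
    std::memcpy(out.begin() + (std::size_t)i * (na + nb) + na,
                b.begin() + (std::size_t)i * nb, nb * sizeof(double));
  }
  return out;
}

// [[Rcpp::export(name = ".split_channels")]]
List split_channels_cpp(NumericVector x, int c_first) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0], C = d[1], B = d[2];
  const int Cb = C - c_first;
  NumericVector a(Dimension(HW, c_first, B)), b(Dimension(HW, Cb, B));
  const std::size_t na = (std::size_t)HW * c_first, nb = (std::size_t)HW * Cb;
  for (int i = 0; i < B; ++i) {
    std::memcpy(a.begin() + (std::size_t)i * na,
                x.begin() + (std::size_t)i * (na + nb), na * sizeof(double));
    std::memcpy(b.begin() + (std::size_t)i * nb,
                x.begin() + (std::size_t)i * (na + nb) + na,
                nb * sizeof(double));
  }
  return List::create(Named("first") = a, Named("rest") = b);
}
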