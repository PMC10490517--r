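// Low-level kernels for the fusion ConvNets: im2col convolutions on BLAS
// matrix products, batch normalization, ELU, max-pooling, dropout and an
// in-place Adam update. Activation arrays are laid out [time, batch,
// channel] column-major, matching the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_time(const double* x, int T, int B, int C, int k) {
  // rows (t, b), cols (j, c); stride-1 valid windows along time
  const int Tout = T - k + 1;
  arma::mat m(static_cast<size_t>(Tout) * B, static_cast<size_t>(k) * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double* dst = m.colptr(static_cast<size_t>(c) * k + j);
      for (int b = 0; b < B; ++b) {
        const double* src = x + (static_cast<size_t>(c) * B + b) * T + j;
        std::copy(src, src + Tout, dst + static_cast<size_t>(b) * Tout);
      }
    }
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_conv1d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b, int k) {
  const int T = dims[0], B = dims[1], C = dims[2];
  const int Tout = T - k + 1, F = W.ncol();
  arma::mat m = im2col_time(x.begin(), T, B, C, k);
  arma::mat Wm(W.begin(), W.nrow(), F, false);
  arma::mat y = m * Wm;
  y.each_row() += arma::rowvec(b.begin(), F, false);
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Tout, B, F);
  return out;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(NumericVector x, IntegerVector dims, NumericVector dy,
                    NumericMatrix W, int k, bool need_dx) {
  const int T = dims[0], B = dims[1], C = dims[2];
  const int Tout = T - k + 1, F = W.ncol();
  arma::mat m = im2col_time(x.begin(), T, B, C, k);
  arma::mat dym(dy.begin(), static_cast<size_t>(Tout) * B, F, false);
  arma::mat Wm(W.begin(), W.nrow(), F, false);
  arma::mat dW = m.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  List out = List::create(_["dW"] = wrap(dW),
                          _["db"] = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    arma::mat dm = dym * Wm.t();  // rows (t,b), cols (j,c)
    NumericVector dx(static_cast<size_t>(T) * B * C);
    double* dxp = dx.begin();
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < k; ++j) {
        const double* src = dm.colptr(static_cast<size_t>(c) * k + j);
        for (int b = 0; b < B; ++b) {
          double* dst = dxp + (static_cast<size_t>(c) * B + b) * T + j;
          const double* s = src + static_cast<size_t>(b) * Tout;
          for (int t = 0; t < Tout; ++t) dst[t] += s[t];
        }
      }
    }
    dx.attr("dim") = IntegerVector::create(T, B, C);
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, int n, int C, NumericVector gamma,
                NumericVector beta, bool train, NumericVector run_mean,
                NumericVector run_var, double eps) {
  NumericVector y(x.size());
  NumericVector mu(C), var(C), isd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<size_t>(c) * n;
    double m, v;
    if (train) {
      double s = 0, s2 = 0;
      for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m = s / n;
      v = std::max(s2 / n - m * m, 0.0);
    } else {
      m = run_mean[c];
      v = run_var[c];
    }
    mu[c] = m; var[c] = v;
    const double is = 1.0 / std::sqrt(v + eps);
    isd[c] = is;
    const double a = gamma[c] * is;
    const double cc = beta[c] - a * m;
    double* yc = y.begin() + static_cast<size_t>(c) * n;
    for (int i = 0; i < n; ++i) yc[i] = a * xc[i] + cc;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["isd"] = isd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, int n, int C,
                NumericVector gamma, NumericVector mu, NumericVector isd) {
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<size_t>(c) * n;
    const double* dc = dy.begin() + static_cast<size_t>(c) * n;
    const double m = mu[c], is = isd[c];
    double sd = 0, sdx = 0;
    for (int i = 0; i < n; ++i) {
      sd += dc[i];
      sdx += dc[i] * (xc[i] - m) * is;
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double g_is = gamma[c] * is;
    const double mean_d = sd / n, mean_dx = sdx / n;
    double* out = dx.begin() + static_cast<size_t>(c) * n;
    for (int i = 0; i < n; ++i) {
      out[i] = g_is * (dc[i] - mean_d - (xc[i] - m) * is * mean_dx);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_elu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t nn = x.size();
  for (size_t i = 0; i < nn; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : std::expm1(xp[i]);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* dp = dy.begin();
  const double* yp = y.begin();
  double* op = dx.begin();
  const size_t nn = dy.size();
  for (size_t i = 0; i < nn; ++i)
    op[i] = yp[i] > 0 ? dp[i] : dp[i] * (yp[i] + 1.0);
  return dx;
}

// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x, IntegerVector dims) {
  const int T = dims[0];
  const size_t BC = static_cast<size_t>(dims[1]) * dims[2];
  const int Tout = T / 2;
  NumericVector y(Tout * BC);
  LogicalVector first(Tout * BC);
  for (size_t s = 0; s < BC; ++s) {
    const double* xc = x.begin() + s * T;
    double* yc = y.begin() + s * Tout;
    int* fc = first.begin() + s * Tout;
    for (int t = 0; t < Tout; ++t) {
      const double a = xc[2 * t], b = xc[2 * t + 1];
      const bool take_a = a >= b;  // ties take the earlier sample
      yc[t] = take_a ? a : b;
      fc[t] = take_a;
    }
  }
  y.attr("dim") = IntegerVector::create(Tout, dims[1], dims[2]);
  return List::create(_["y"] = y, _["first"] = first);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dy, LogicalVector first,
                           IntegerVector dims) {
  const int T = dims[0];
  const size_t BC = static_cast<size_t>(dims[1]) * dims[2];
  const int Tout = T / 2;
  NumericVector dx(static_cast<size_t>(T) * BC);
  for (size_t s = 0; s < BC; ++s) {
    const double* dc = dy.begin() + s * Tout;
    const int* fc = first.begin() + s * Tout;
    double* xc = dx.begin() + s * T;
    for (int t = 0; t < Tout; ++t) {
      xc[2 * t + (fc[t] ? 0 : 1)] = dc[t];
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// [[Rcpp::export]]
List cpp_dropout(NumericVector x, double p) {
  // uses R's RNG so results are reproducible under set.seed()
  NumericVector y(x.size()), mask(x.size());
  const double scale = 1.0 / (1.0 - p);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* mp = mask.begin();
  const size_t nn = x.size();
  GetRNGstate();
  for (size_t i = 0; i < nn; ++i) {
    const double m = unif_rand() >= p ? scale : 0.0;
    mp[i] = m;
    yp[i] = xp[i] * m;
  }
  PutRNGstate();
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
void cpp_adam(NumericVector param, NumericVector m, NumericVector v,
              NumericVector grad, double alpha, double b1, double b2,
              double eps_t) {
  // in place: caller guarantees exclusive ownership of param/m/v
  double* p = param.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  const double* g = grad.begin();
  const size_t nn = param.size();
  for (size_t i = 0; i < nn; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * g[i];
    vp[i] = b2 * vp[i] + (1 - b2) * g[i] * g[i];
    p[i] -= alpha * mp[i] / (std::sqrt(vp[i]) + eps_t);
  }
}

// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  // direct-form II transposed with initial state zi (length = order)
  const int n = x.size(), nz = zi.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nz ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (nz) z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
  return y;
}
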