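// Fused elementwise kernels for the network hot paths. Matrix products stay
// in R (BLAS); these kernels fuse the broadcast/elementwise chains that
// dominate interpreted execution time.

#include <Rcpp.h>
using namespace Rcpp;

// Y = X + row-broadcast b
// [[Rcpp::export]]
NumericMatrix cpp_addrow(const NumericMatrix& X, const NumericVector& b) {
  const int n = X.nrow(), c = X.ncol();
  NumericMatrix Y(n, c);
  for (int j = 0; j < c; ++j) {
    const double bj = b[j];
    const double* x = &X(0, j);
    double* y = &Y(0, j);
    for (int i = 0; i < n; ++i) y[i] = x[i] + bj;
  }
  return Y;
}

// batch-norm forward; training mode computes batch statistics
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& X, const NumericVector& gamma,
                const NumericVector& beta, const NumericVector& mean_in,
                const NumericVector& var_in, const bool training,
                const double eps) {
  const int n = X.nrow(), c = X.ncol();
  NumericMatrix Y(n, c), Xhat(n, c);
  NumericVector mu(c), va(c), inv(c);
  for (int j = 0; j < c; ++j) {
    const double* x = &X(0, j);
    double m, v;
    if (training) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += x[i];
      m = s / n;
      double sq = 0.0;
      for (int i = 0; i < n; ++i) { const double d = x[i] - m; sq += d * d; }
      v = sq / n;
    } else {
      m = mean_in[j];
      v = var_in[j];
    }
    const double iv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[j], b = beta[j];
    double* xh = &Xhat(0, j);
    double* y = &Y(0, j);
    for (int i = 0; i < n; ++i) {
      xh[i] = (x[i] - m) * iv;
      y[i] = g * xh[i] + b;
    }
    mu[j] = m; va[j] = v; inv[j] = iv;
  }
  return List::create(_["Y"] = Y, _["Xhat"] = Xhat, _["inv"] = inv,
                      _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericVector& gamma,
                const NumericMatrix& Xhat, const NumericVector& inv,
                const bool training) {
  const int n = dY.nrow(), c = dY.ncol();
  NumericMatrix dX(n, c);
  NumericVector dgamma(c), dbeta(c);
  for (int j = 0; j < c; ++j) {
    const double* dy = &dY(0, j);
    const double* xh = &Xhat(0, j);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) { sg += dy[i] * xh[i]; sb += dy[i]; }
    dgamma[j] = sg; dbeta[j] = sb;
    double* dx = &dX(0, j);
    const double g = gamma[j], iv = inv[j];
    if (!training) {
      for (int i = 0; i < n; ++i) dx[i] = dy[i] * g * iv;
    } else {
      const double mdx = g * sb / n;          // mean of dXhat
      const double mdxx = g * sg / n;         // mean of dXhat * Xhat
      for (int i = 0; i < n; ++i)
        dx[i] = (dy[i] * g - mdx - xh[i] * mdxx) * iv;
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_prelu_fwd(const NumericMatrix& X, const NumericVector& a) {
  const int n = X.nrow(), c = X.ncol();
  NumericMatrix Y(n, c);
  for (int j = 0; j < c; ++j) {
    const double aj = a[j];
    const double* x = &X(0, j);
    double* y = &Y(0, j);
    for (int i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : aj * x[i];
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_prelu_bwd(const NumericMatrix& dY, const NumericMatrix& X,
                   const NumericVector& a) {
  const int n = X.nrow(), c = X.ncol();
  NumericMatrix dX(n, c);
  NumericVector da(c);
  for (int j = 0; j < c; ++j) {
    const double aj = a[j];
    const double* x = &X(0, j);
    const double* dy = &dY(0, j);
    double* dx = &dX(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (x[i] > 0) {
        dx[i] = dy[i];
      } else {
        dx[i] = aj * dy[i];
        s += dy[i] * x[i];
      }
    }
    da[j] = s;
  }
  return List::create(_["dX"] = dX, _["da"] = da);
}

// max pooling over row pairs (r1, r2 are 1-based duplicate-free row maps)
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& X, const IntegerVector& r1,
                     const IntegerVector& r2) {
  const int m = r1.size(), c = X.ncol();
  NumericMatrix Y(m, c);
  LogicalMatrix take1(m, c);
  for (int j = 0; j < c; ++j) {
    const double* x = &X(0, j);
    double* y = &Y(0, j);
    for (int i = 0; i < m; ++i) {
      const double a = x[r1[i] - 1], b = x[r2[i] - 1];
      if (a >= b) { y[i] = a; take1(i, j) = true; }
      else { y[i] = b; take1(i, j) = false; }
    }
  }
  return List::create(_["Y"] = Y, _["take1"] = take1);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dY,
                              const LogicalMatrix& take1,
                              const IntegerVector& r1, const IntegerVector& r2,
                              const int nrow_X) {
  const int m = r1.size(), c = dY.ncol();
  NumericMatrix dX(nrow_X, c);
  for (int j = 0; j < c; ++j) {
    const double* dy = &dY(0, j);
    double* dx = &dX(0, j);
    for (int i = 0; i < m; ++i) {
      if (take1(i, j)) dx[r1[i] - 1] += dy[i];
      else dx[r2[i] - 1] += dy[i];
    }
  }
  return dX;
}

// gather kernel columns: idx is (n*L) x k of 1-based source rows, 0 = pad
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int rows = idx.nrow(), k = idx.ncol(), cin = X.ncol();
  NumericMatrix Xcol(rows, k * cin);
  for (int o = 0; o < k; ++o) {
    const int* id = &idx(0, o);
    for (int j = 0; j < cin; ++j) {
      const double* x = &X(0, j);
      double* y = &Xcol(0, o * cin + j);
      for (int i = 0; i < rows; ++i) {
        const int s = id[i];
        y[i] = s > 0 ? x[s - 1] : 0.0;
      }
    }
  }
  return Xcol;
}

// scatter-accumulate conv gradient back to the input rows
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dXcol, const IntegerMatrix& idx,
                         const int nrow_X, const int cin) {
  const int rows = idx.nrow(), k = idx.ncol();
  NumericMatrix dX(nrow_X, cin);
  for (int o = 0; o < k; ++o) {
    const int* id = &idx(0, o);
    for (int j = 0; j < cin; ++j) {
      const double* dy = &dXcol(0, o * cin + j);
      double* dx = &dX(0, j);
      for (int i = 0; i < rows; ++i) {
        const int s = id[i];
        if (s > 0) dx[s - 1] += dy[i];
      }
    }
  }
  return dX;
}

// GRU gate elementwise stage 1: Z, R from pre-activations, plus R*H
// [[Rcpp::export]]
List cpp_gru_gates(const NumericMatrix& Az, const NumericMatrix& Ar,
                   const NumericVector& bz, const NumericVector& br,
                   const NumericMatrix& H) {
  const int n = H.nrow(), c = H.ncol();
  NumericMatrix Z(n, c), R(n, c), RH(n, c);
  for (int j = 0; j < c; ++j) {
    const double bzj = bz[j], brj = br[j];
    const double* az = &Az(0, j);
    const double* ar = &Ar(0, j);
    const double* h = &H(0, j);
    double* z = &Z(0, j); double* r = &R(0, j); double* rh = &RH(0, j);
    for (int i = 0; i < n; ++i) {
      z[i] = 1.0 / (1.0 + std::exp(-(az[i] + bzj)));
      r[i] = 1.0 / (1.0 + std::exp(-(ar[i] + brj)));
      rh[i] = r[i] * h[i];
    }
  }
  return List::create(_["Z"] = Z, _["R"] = R, _["RH"] = RH);
}

// GRU elementwise stage 2: candidate and gated output
// [[Rcpp::export]]
List cpp_gru_out(const NumericMatrix& Gc, const NumericVector& bc,
                 const NumericMatrix& H, const NumericMatrix& Z) {
  const int n = H.nrow(), c = H.ncol();
  NumericMatrix C(n, c), Hn(n, c);
  for (int j = 0; j < c; ++j) {
    const double bcj = bc[j];
    const double* gc = &Gc(0, j);
    const double* h = &H(0, j);
    const double* z = &Z(0, j);
    double* cc = &C(0, j); double* hn = &Hn(0, j);
    for (int i = 0; i < n; ++i) {
      cc[i] = std::tanh(gc[i] + bcj);
      hn[i] = (1.0 - z[i]) * h[i] + z[i] * cc[i];
    }
  }
  return List::create(_["C"] = C, _["Hn"] = Hn);
}

// GRU backward elementwise stage 1: through the output gate and candidate
// [[Rcpp::export]]
List cpp_gru_bwd1(const NumericMatrix& dHn, const NumericMatrix& H,
                  const NumericMatrix& Z, const NumericMatrix& C) {
  const int n = H.nrow(), c = H.ncol();
  NumericMatrix dGc(n, c), dGz(n, c), dH(n, c);
  for (int j = 0; j < c; ++j) {
    const double* dhn = &dHn(0, j);
    const double* h = &H(0, j);
    const double* z = &Z(0, j);
    const double* cc = &C(0, j);
    double* dgc = &dGc(0, j); double* dgz = &dGz(0, j); double* dh = &dH(0, j);
    for (int i = 0; i < n; ++i) {
      dgc[i] = dhn[i] * z[i] * (1.0 - cc[i] * cc[i]);
      dgz[i] = dhn[i] * (cc[i] - h[i]) * z[i] * (1.0 - z[i]);
      dh[i] = dhn[i] * (1.0 - z[i]);
    }
  }
  return List::create(_["dGc"] = dGc, _["dGz"] = dGz, _["dH"] = dH);
}

// GRU backward elementwise stage 2: through the reset gate
// [[Rcpp::export]]
List cpp_gru_bwd2(const NumericMatrix& dRH, const NumericMatrix& H,
                  const NumericMatrix& R) {
  const int n = H.nrow(), c = H.ncol();
  NumericMatrix dGr(n, c), dH2(n, c);
  for (int j = 0; j < c; ++j) {
    const double* drh = &dRH(0, j);
    const double* h = &H(0, j);
    const double* r = &R(0, j);
    double* dgr = &dGr(0, j); double* dh = &dH2(0, j);
    for (int i = 0; i < n; ++i) {
      dgr[i] = drh[i] * h[i] * r[i] * (1.0 - r[i]);
      dh[i] = drh[i] * r[i];
    }
  }
  return List::create(_["dGr"] = dGr, _["dH2"] = dH2);
}

// fused Adam update; returns fresh p, m, v vectors
// [[Rcpp::export]]
List cpp_adam(const NumericVector& p, const NumericVector& g,
              const NumericVector& m, const NumericVector& v, const int t,
              const double lr, const double b1, const double b2,
              const double eps) {
  const int n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (int i = 0; i < n; ++i) {
    m2[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v2[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p2[i] = p[i] - lr * (m2[i] / c1) / (std::sqrt(v2[i] / c2) + eps);
  }
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
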