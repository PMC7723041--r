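// Fused compute kernels for the 1D-convolutional networks.
//
// Activations with a temporal axis are position-major: a batch of n
// sequences of length L with C channels is an (n*L) x C matrix whose row
// block t holds all n samples at time t. All kernels preserve that layout.
// Dropout draws from R's RNG so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kernel-2 "same"-padded convolution: Z = A W1 + shift(A) W2 + b, where
// shift advances the position index by one (zero-padded tail).
// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& A, int n, const arma::mat& W1,
                       const arma::mat& W2, const arma::vec& b) {
  const arma::uword nL = A.n_rows;
  arma::mat Z = A * W1;
  Z.rows(0, nL - n - 1) += A.rows(n, nL - 1) * W2;
  Z.each_row() += b.t();
  return Z;
}

// Convolution fused with ReLU: returns max(Z, 0). The pre-activation sign
// needed by backprop is recoverable from the output (> 0).
// [[Rcpp::export]]
arma::mat cpp_conv_relu_fwd(const arma::mat& A, int n, const arma::mat& W1,
                            const arma::mat& W2, const arma::vec& b) {
  const arma::uword nL = A.n_rows;
  arma::mat Z = A * W1;
  Z.rows(0, nL - n - 1) += A.rows(n, nL - 1) * W2;
  Z.each_row() += b.t();
  Z.transform([](double v) { return v > 0 ? v : 0.0; });
  return Z;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& A, const arma::mat& dZ, const arma::mat& W1,
                  const arma::mat& W2, int n, bool need_dA) {
  const arma::uword nL = A.n_rows;
  arma::mat dW1 = A.t() * dZ;
  arma::mat dW2 = A.rows(n, nL - 1).t() * dZ.rows(0, nL - n - 1);
  arma::rowvec db = arma::sum(dZ, 0);
  if (!need_dA) {
    return List::create(_["dW1"] = dW1, _["dW2"] = dW2, _["db"] = db);
  }
  arma::mat dA = dZ * W1.t();
  dA.rows(n, nL - 1) += dZ.rows(0, nL - n - 1) * W2.t();
  return List::create(_["dW1"] = dW1, _["dW2"] = dW2, _["db"] = db,
                      _["dA"] = dA);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_fwd(NumericMatrix Z) {
  NumericMatrix A(Z.nrow(), Z.ncol());
  const double* z = Z.begin();
  double* a = A.begin();
  const R_xlen_t m = Z.size();
  for (R_xlen_t i = 0; i < m; ++i) a[i] = z[i] > 0 ? z[i] : 0.0;
  return A;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix dA, NumericMatrix Z) {
  NumericMatrix dZ(dA.nrow(), dA.ncol());
  const double* d = dA.begin();
  const double* z = Z.begin();
  double* o = dZ.begin();
  const R_xlen_t m = dA.size();
  for (R_xlen_t i = 0; i < m; ++i) o[i] = z[i] > 0 ? d[i] : 0.0;
  return dZ;
}

// Non-overlapping size-2 max pooling along the position axis.
// Returns the pooled matrix and a logical mask (TRUE = first of the pair).
// [[Rcpp::export]]
List cpp_pool_fwd(NumericMatrix A, int n, int L) {
  const int Lout = L / 2;
  const int C = A.ncol();
  NumericMatrix P(n * Lout, C);
  LogicalMatrix take1(n * Lout, C);
  for (int c = 0; c < C; ++c) {
    const double* a = &A(0, c);
    double* p = &P(0, c);
    int* t1 = &take1(0, c);
    for (int q = 0; q < Lout; ++q) {
      const double* a1 = a + (2 * q) * n;
      const double* a2 = a + (2 * q + 1) * n;
      double* pp = p + q * n;
      int* tt = t1 + q * n;
      for (int i = 0; i < n; ++i) {
        if (a1[i] >= a2[i]) { pp[i] = a1[i]; tt[i] = 1; }
        else { pp[i] = a2[i]; tt[i] = 0; }
      }
    }
  }
  return List::create(_["P"] = P, _["take1"] = take1);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(NumericMatrix dP, LogicalMatrix take1, int n, int L) {
  const int Lout = L / 2;
  const int C = dP.ncol();
  NumericMatrix dA(n * L, C);  // zero-initialized (odd trailing position stays 0)
  for (int c = 0; c < C; ++c) {
    const double* dp = &dP(0, c);
    const int* t1 = &take1(0, c);
    double* da = &dA(0, c);
    for (int q = 0; q < Lout; ++q) {
      const double* dpp = dp + q * n;
      const int* tt = t1 + q * n;
      double* d1 = da + (2 * q) * n;
      double* d2 = da + (2 * q + 1) * n;
      for (int i = 0; i < n; ++i) {
        if (tt[i]) d1[i] = dpp[i]; else d2[i] = dpp[i];
      }
    }
  }
  return dA;
}

// Pool backward fused with the ReLU backward of the preceding activation:
// scatters dP to the argmax position and zeroes it where the post-ReLU
// activation A was 0 (i.e. the pre-activation was negative).
// [[Rcpp::export]]
NumericMatrix cpp_pool_relu_bwd(NumericMatrix dP, LogicalMatrix take1,
                                NumericMatrix A, int n, int L) {
  const int Lout = L / 2;
  const int C = dP.ncol();
  NumericMatrix dZ(n * L, C);
  for (int c = 0; c < C; ++c) {
    const double* dp = &dP(0, c);
    const int* t1 = &take1(0, c);
    const double* a = &A(0, c);
    double* dz = &dZ(0, c);
    for (int q = 0; q < Lout; ++q) {
      const double* dpp = dp + q * n;
      const int* tt = t1 + q * n;
      for (int i = 0; i < n; ++i) {
        const int off = tt[i] ? (2 * q) * n + i : (2 * q + 1) * n + i;
        if (a[off] > 0) dz[off] = dpp[i];
      }
    }
  }
  return dZ;
}

// Batch norm forward over rows per column. Returns normalized output plus
// the per-column batch statistics needed for backprop / running averages.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix X, NumericVector gamma, NumericVector beta,
                NumericVector use_mean, NumericVector use_var,
                bool compute_stats, double eps) {
  const int m = X.nrow(), C = X.ncol();
  NumericMatrix Y(m, C), xhat(m, C);
  NumericVector mu(C), var(C), inv_std(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double mc, vc;
    if (compute_stats) {
      double s = 0;
      for (int i = 0; i < m; ++i) s += x[i];
      mc = s / m;
      double ss = 0;
      for (int i = 0; i < m; ++i) { double d = x[i] - mc; ss += d * d; }
      vc = ss / m;
    } else {
      mc = use_mean[c];
      vc = use_var[c];
    }
    mu[c] = mc; var[c] = vc;
    const double is = 1.0 / std::sqrt(vc + eps);
    inv_std[c] = is;
    const double g = gamma[c], be = beta[c];
    double* y = &Y(0, c);
    double* xh = &xhat(0, c);
    for (int i = 0; i < m; ++i) {
      xh[i] = (x[i] - mc) * is;
      y[i] = g * xh[i] + be;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["inv_std"] = inv_std,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dY, NumericMatrix xhat, NumericVector inv_std,
                NumericVector gamma) {
  const int m = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    const double g = gamma[c], is = inv_std[c];
    double s1 = 0, sg = 0;
    for (int i = 0; i < m; ++i) {
      s1 += dy[i];
      sg += dy[i] * xh[i];
    }
    dgamma[c] = sg;
    dbeta[c] = s1;
    const double a1 = g * s1 / m, a2 = g * sg / m;
    double* dx = &dX(0, c);
    for (int i = 0; i < m; ++i) {
      dx[i] = is * (dy[i] * g - a1 - xh[i] * a2);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inverted dropout using R's RNG stream (reproducible under set.seed).
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericMatrix X, double p) {
  const R_xlen_t m = X.size();
  NumericMatrix Y(X.nrow(), X.ncol());
  NumericMatrix mask(X.nrow(), X.ncol());
  const double keep = 1.0 - p;
  const double scale = 1.0 / keep;
  const double* x = X.begin();
  double* y = Y.begin();
  double* mk = mask.begin();
  GetRNGstate();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double u = unif_rand();
    if (u < keep) { mk[i] = scale; y[i] = x[i] * scale; }
    else { mk[i] = 0.0; y[i] = 0.0; }
  }
  PutRNGstate();
  return List::create(_["Y"] = Y, _["mask"] = mask);
}
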