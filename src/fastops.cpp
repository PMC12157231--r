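// Fused elementwise kernels for the PointNet training loop. Activations are
// feature-major (features x observations, column-major), so the inner loops
// over features run over contiguous memory. Matrix products are left to the
// BLAS via R's crossprod/tcrossprod.

#include <Rcpp.h>
using namespace Rcpp;

// Batch-normalisation + ReLU forward over a feature-major activation block.
// Returns the ReLU output, the normalized activations (needed by the
// backward pass), the inverse standard deviations, and the batch mean/var
// for the running-statistics update. In eval mode the supplied running
// statistics are used instead of batch statistics.
// [[Rcpp::export(name = ".bn_relu_forward")]]
List bn_relu_forward(NumericMatrix Z, NumericVector gamma,
                     NumericVector beta, NumericVector rmean,
                     NumericVector rvar, double eps, bool train) {
  const int F = Z.nrow(), N = Z.ncol();
  NumericVector mu(F), var(F), invstd(F);
  if (train) {
    for (int j = 0; j < N; ++j) {
      const double* z = &Z(0, j);
      for (int f = 0; f < F; ++f) mu[f] += z[f];
    }
    for (int f = 0; f < F; ++f) mu[f] /= N;
    for (int j = 0; j < N; ++j) {
      const double* z = &Z(0, j);
      for (int f = 0; f < F; ++f) {
        const double d = z[f] - mu[f];
        var[f] += d * d;
      }
    }
    for (int f = 0; f < F; ++f) {
      var[f] /= N;
      invstd[f] = 1.0 / std::sqrt(var[f] + eps);
    }
  } else {
    for (int f = 0; f < F; ++f) {
      mu[f] = rmean[f];
      invstd[f] = 1.0 / std::sqrt(rvar[f] + eps);
    }
  }
  NumericMatrix A(F, N), xhat(F, N);
  for (int j = 0; j < N; ++j) {
    const double* z = &Z(0, j);
    double* a = &A(0, j);
    double* xh = &xhat(0, j);
    for (int f = 0; f < F; ++f) {
      const double x = (z[f] - mu[f]) * invstd[f];
      xh[f] = x;
      const double y = x * gamma[f] + beta[f];
      a[f] = y > 0.0 ? y : 0.0;
    }
  }
  return List::create(_["A"] = A, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["var"] = var);
}

// Backward pass through ReLU + batch normalisation. dA is the gradient at
// the ReLU output; A is the forward ReLU output (its zeros encode the mask).
// Returns the gradient at the linear pre-activation plus the per-feature
// parameter gradients (including the bias of the preceding linear layer,
// which equals the row sums of dZ).
// [[Rcpp::export(name = ".bn_relu_backward")]]
List bn_relu_backward(NumericMatrix dA, NumericMatrix A, NumericMatrix xhat,
                      NumericVector invstd, NumericVector gamma) {
  const int F = dA.nrow(), N = dA.ncol();
  NumericVector dgamma(F), dbeta(F), s2(F);
  for (int j = 0; j < N; ++j) {
    const double* da = &dA(0, j);
    const double* a = &A(0, j);
    const double* xh = &xhat(0, j);
    for (int f = 0; f < F; ++f) {
      if (a[f] > 0.0) {
        const double g = da[f];
        dbeta[f] += g;
        dgamma[f] += g * xh[f];
      }
    }
  }
  for (int f = 0; f < F; ++f) s2[f] = dgamma[f] * gamma[f] / N;
  NumericVector s1(F);
  for (int f = 0; f < F; ++f) s1[f] = dbeta[f] * gamma[f] / N;
  NumericMatrix dZ(F, N);
  NumericVector dbias(F);
  for (int j = 0; j < N; ++j) {
    const double* da = &dA(0, j);
    const double* a = &A(0, j);
    const double* xh = &xhat(0, j);
    double* dz = &dZ(0, j);
    for (int f = 0; f < F; ++f) {
      const double dxhat = a[f] > 0.0 ? da[f] * gamma[f] : 0.0;
      const double v = (dxhat - xh[f] * s2[f] - s1[f]) * invstd[f];
      dz[f] = v;
      dbias[f] += v;
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta, _["dbias"] = dbias);
}

// Column-block max pooling: A is F x (B*P) with sample-major column blocks;
// returns the per-sample feature maxima (F x B) and 1-based argmax offsets.
// [[Rcpp::export(name = ".block_max_pool")]]
List block_max_pool(NumericMatrix A, int B, int P) {
  const int F = A.nrow();
  NumericMatrix G(F, B);
  IntegerMatrix Arg(F, B);
  for (int b = 0; b < B; ++b) {
    double* g = &G(0, b);
    int* arg = &Arg(0, b);
    const double* a0 = &A(0, b * P);
    for (int f = 0; f < F; ++f) { g[f] = a0[f]; arg[f] = 1; }
    for (int p = 1; p < P; ++p) {
      const double* a = &A(0, (b * P + p));
      for (int f = 0; f < F; ++f) {
        if (a[f] > g[f]) { g[f] = a[f]; arg[f] = p + 1; }
      }
    }
  }
  return List::create(_["G"] = G, _["Arg"] = Arg);
}

// Scatter of the pooled gradient back to the argmax positions.
// [[Rcpp::export(name = ".block_max_pool_backward")]]
NumericMatrix block_max_pool_backward(NumericMatrix dG, IntegerMatrix Arg,
                                      int B, int P) {
  const int F = dG.nrow();
  NumericMatrix dA(F, B * P);
  for (int b = 0; b < B; ++b) {
    const double* dg = &dG(0, b);
    const int* arg = &Arg(0, b);
    for (int f = 0; f < F; ++f) {
      dA(f, b * P + arg[f] - 1) = dg[f];
    }
  }
  return dA;
}

// One fused Adam update with optional L2 regularisation (added to the raw
// gradient, as in classic L2-regularised Adam). The first-moment and
// second-moment buffers are updated in place (they are owned exclusively by
// the optimizer state); the updated parameter tensor is returned as a fresh
// object.
// [[Rcpp::export(name = ".adam_update")]]
SEXP adam_update(SEXP p_, NumericVector g, NumericVector m, NumericVector v,
                 double lr, double b1, double b2, double corr1, double corr2,
                 double eps, double weight_decay) {
  NumericVector p(p_);
  R_xlen_t n = p.size();
  NumericVector out = clone(p);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + weight_decay * out[i];
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    out[i] -= lr * (m[i] / corr1) / (std::sqrt(v[i] / corr2) + eps);
  }
  return out;
}
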