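// Hot inner kernels of the neural-network core. Only memory-bound
// elementwise and indexing operations live here; all matrix products stay
// in R so they run through BLAS.
#include <Rcpp.h>
using namespace Rcpp;

// im2col gather: x is (ns x C), idx is (ns x k) with 0 marking a padded
// position. Output column q = (c) * k + j (channel-major, tap fastest),
// matching the kernel matrix row order.
// `out` is a caller-owned (ns x k*ch) buffer reused across batches.
// [[Rcpp::export]]
NumericMatrix cpp_conv_gather(const NumericMatrix& x,
                              const IntegerMatrix& idx, NumericMatrix out) {
  const int ns = idx.nrow(), k = idx.ncol(), ch = x.ncol();
  for (int c = 0; c < ch; ++c) {
    const double* xc = &x(0, c);
    for (int j = 0; j < k; ++j) {
      double* oc = &out(0, c * k + j);
      const int* ij = &idx(0, j);
      for (int r = 0; r < ns; ++r) {
        const int s = ij[r];
        oc[r] = s > 0 ? xc[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// Backward scatter: accumulate dxcol (ns x k*ch) back onto the input grid.
// [[Rcpp::export]]
NumericMatrix cpp_conv_scatter(const NumericMatrix& dxcol,
                               const IntegerMatrix& idx, const int ch) {
  const int ns = idx.nrow(), k = idx.ncol();
  NumericMatrix dx(ns, ch);
  for (int c = 0; c < ch; ++c) {
    double* dc = &dx(0, c);
    for (int j = 0; j < k; ++j) {
      const double* sc = &dxcol(0, c * k + j);
      const int* ij = &idx(0, j);
      for (int r = 0; r < ns; ++r) {
        const int s = ij[r];
        if (s > 0) dc[s - 1] += sc[r];
      }
    }
  }
  return dx;
}

// Batch-norm training forward: per-column batch statistics (biased
// variance). The scaled output is written into the caller-owned buffer `y`;
// the input tensor itself is cached R-side, so the normalised tensor is
// never materialised.
// [[Rcpp::export]]
List cpp_bn_train(const NumericMatrix& x, const NumericVector& gamma,
                  const NumericVector& beta, const double eps,
                  NumericMatrix y) {
  const int m = x.nrow(), ch = x.ncol();
  NumericVector mu(ch), var(ch), inv(ch);
  for (int c = 0; c < ch; ++c) {
    const double* xc = &x(0, c);
    double s = 0.0, s2 = 0.0;
    for (int r = 0; r < m; ++r) s += xc[r];
    const double mean = s / m;
    for (int r = 0; r < m; ++r) {
      const double d = xc[r] - mean;
      s2 += d * d;
    }
    const double v = s2 / m;
    const double iv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double* yc = &y(0, c);
    for (int r = 0; r < m; ++r) yc[r] = g * (xc[r] - mean) * iv + b;
    mu[c] = mean; var[c] = v; inv[c] = iv;
  }
  return List::create(_["mu"] = mu, _["var"] = var, _["inv"] = inv);
}

// [[Rcpp::export]]
NumericMatrix cpp_bn_infer(const NumericMatrix& x, const NumericVector& gamma,
                           const NumericVector& beta,
                           const NumericVector& rmean,
                           const NumericVector& rvar, const double eps) {
  const int m = x.nrow(), ch = x.ncol();
  NumericMatrix y(m, ch);
  for (int c = 0; c < ch; ++c) {
    const double iv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], b = beta[c], mean = rmean[c];
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int r = 0; r < m; ++r) yc[r] = g * (xc[r] - mean) * iv + b;
  }
  return y;
}

// In place: dy is overwritten with dx (the caller owns dy as a backward
// temporary and never reuses it). The normalised tensor is recomputed on
// the fly from the cached layer input.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dy, const NumericMatrix& x,
                const NumericVector& mu, const NumericVector& inv,
                const NumericVector& gamma) {
  const int m = dy.nrow(), ch = dy.ncol();
  NumericVector dgamma(ch), dbeta(ch);
  for (int c = 0; c < ch; ++c) {
    double* dc = &dy(0, c);
    const double* xc = &x(0, c);
    const double mean = mu[c], iv = inv[c];
    double sg = 0.0, sb = 0.0;
    for (int r = 0; r < m; ++r) {
      sg += dc[r] * (xc[r] - mean) * iv;
      sb += dc[r];
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c];
    const double m1 = sb / m, m2 = sg / m;
    for (int r = 0; r < m; ++r) {
      dc[r] = g * iv * (dc[r] - m1 - (xc[r] - mean) * iv * m2);
    }
  }
  return List::create(_["dx"] = dy, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// In place: x is a forward temporary owned by the calling layer chain.
// [[Rcpp::export]]
NumericMatrix cpp_relu(NumericMatrix x) {
  const int n = x.nrow() * x.ncol();
  double* xp = x.begin();
  for (int i = 0; i < n; ++i) {
    if (xp[i] < 0) xp[i] = 0.0;
  }
  return x;
}

// Uses the activation itself to gate the gradient (y > 0 <=> x > 0).
// In place: dy is overwritten.
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix dy, const NumericMatrix& y) {
  const int n = dy.nrow() * dy.ncol();
  double* dp = dy.begin();
  const double* yp = y.begin();
  for (int i = 0; i < n; ++i) {
    if (yp[i] <= 0) dp[i] = 0.0;
  }
  return dy;
}

// 2x2 max pooling over 4 candidate source rows per output row; ties keep
// the earliest candidate.
// [[Rcpp::export]]
List cpp_pool4_fwd(const NumericMatrix& x, const IntegerVector& r1,
                   const IntegerVector& r2, const IntegerVector& r3,
                   const IntegerVector& r4) {
  const int no = r1.size(), ch = x.ncol();
  NumericMatrix y(no, ch);
  IntegerMatrix arg(no, ch);
  for (int c = 0; c < ch; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    int* ac = &arg(0, c);
    for (int r = 0; r < no; ++r) {
      double m = xc[r1[r] - 1];
      int a = 1;
      double v = xc[r2[r] - 1];
      if (v > m) { m = v; a = 2; }
      v = xc[r3[r] - 1];
      if (v > m) { m = v; a = 3; }
      v = xc[r4[r] - 1];
      if (v > m) { m = v; a = 4; }
      yc[r] = m; ac[r] = a;
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool4_bwd(const NumericMatrix& dy, const IntegerMatrix& arg,
                            const IntegerVector& r1, const IntegerVector& r2,
                            const IntegerVector& r3, const IntegerVector& r4,
                            const int ns) {
  const int no = dy.nrow(), ch = dy.ncol();
  NumericMatrix dx(ns, ch);
  for (int c = 0; c < ch; ++c) {
    const double* dc = &dy(0, c);
    const int* ac = &arg(0, c);
    double* xc = &dx(0, c);
    for (int r = 0; r < no; ++r) {
      int tgt;
      switch (ac[r]) {
        case 1: tgt = r1[r]; break;
        case 2: tgt = r2[r]; break;
        case 3: tgt = r3[r]; break;
        default: tgt = r4[r]; break;
      }
      xc[tgt - 1] += dc[r];
    }
  }
  return dx;
}

// Size-2 max pooling (1-D); ties keep the earlier time step.
// [[Rcpp::export]]
List cpp_pool2_fwd(const NumericMatrix& x, const IntegerVector& r1,
                   const IntegerVector& r2) {
  const int no = r1.size(), ch = x.ncol();
  NumericMatrix y(no, ch);
  LogicalMatrix sel(no, ch);
  for (int c = 0; c < ch; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    int* sc = &sel(0, c);
    for (int r = 0; r < no; ++r) {
      const double a = xc[r1[r] - 1], b = xc[r2[r] - 1];
      const bool first = a >= b;
      yc[r] = first ? a : b;
      sc[r] = first;
    }
  }
  return List::create(_["y"] = y, _["sel"] = sel);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool2_bwd(const NumericMatrix& dy, const LogicalMatrix& sel,
                            const IntegerVector& r1, const IntegerVector& r2,
                            const int ns) {
  const int no = dy.nrow(), ch = dy.ncol();
  NumericMatrix dx(ns, ch);
  for (int c = 0; c < ch; ++c) {
    const double* dc = &dy(0, c);
    const int* sc = &sel(0, c);
    double* xc = &dx(0, c);
    for (int r = 0; r < no; ++r) {
      xc[(sc[r] ? r1[r] : r2[r]) - 1] += dc[r];
    }
  }
  return dx;
}

// In-place Adam update; p, m and v are owned by the layer and updated
// without allocation. Weight decay (2 * l2 * p) is folded into the gradient.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector m, NumericVector v,
                     const NumericVector& g, const double lr, const double b1,
                     const double b2, const double eps, const int step,
                     const double l2) {
  const int n = p.size();
  const double c1 = 1.0 - std::pow(b1, step);
  const double c2 = 1.0 - std::pow(b2, step);
  for (int i = 0; i < n; ++i) {
    double gi = g[i];
    if (l2 > 0) gi += 2.0 * l2 * p[i];
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
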