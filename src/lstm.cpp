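// Full LSTM forward/backward (last-hidden-state variant) in Armadillo, so
// the 12-step BPTT loop runs without interpreter overhead. Gate order is
// (i, f, g, o); matrix products go through the same BLAS R uses.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::uvec step_rows(const int t, const int n, const int len) {
  arma::uvec r(n);
  for (int i = 0; i < n; ++i) r[i] = t + (arma::uword)i * len;
  return r;
}

// x: (n*len) x C sample-major; Wx: C x 4U; Wh: U x 4U; b: 4U.
// `buf` is a caller-owned cache of length n*U*len*6 reused across batches;
// slice order per time step: i, f, g, o, tanh(c), c_prev.
// [[Rcpp::export]]
arma::mat cpp_lstm_fwd(const arma::mat& x, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::rowvec& b,
                       const int n, const int len, NumericVector buf) {
  const int U = Wh.n_rows;
  arma::cube K(buf.begin(), n, U, 6 * len, false, true);
  arma::mat xw = x * Wx;
  xw.each_row() += b;
  arma::mat h(n, U, arma::fill::zeros), c(n, U, arma::fill::zeros);
  for (int t = 0; t < len; ++t) {
    const arma::uvec rows = step_rows(t, n, len);
    arma::mat z = xw.rows(rows) + h * Wh;
    K.slice(6 * t + 0) = 1.0 / (1.0 + arma::exp(-z.cols(0, U - 1)));
    K.slice(6 * t + 1) = 1.0 / (1.0 + arma::exp(-z.cols(U, 2 * U - 1)));
    K.slice(6 * t + 2) = arma::tanh(z.cols(2 * U, 3 * U - 1));
    K.slice(6 * t + 3) = 1.0 / (1.0 + arma::exp(-z.cols(3 * U, 4 * U - 1)));
    K.slice(6 * t + 5) = c;
    c = K.slice(6 * t + 1) % c + K.slice(6 * t + 0) % K.slice(6 * t + 2);
    K.slice(6 * t + 4) = arma::tanh(c);
    h = K.slice(6 * t + 3) % K.slice(6 * t + 4);
  }
  return h;
}

// [[Rcpp::export]]
List cpp_lstm_bwd(arma::mat dh, const arma::mat& x, const arma::mat& Wx,
                  const arma::mat& Wh, NumericVector buf, const int n,
                  const int len) {
  const int U = Wh.n_rows;
  const arma::cube K(buf.begin(), n, U, 6 * len, false, true);
  arma::mat dWx(Wx.n_rows, Wx.n_cols, arma::fill::zeros);
  arma::mat dWh(U, 4 * U, arma::fill::zeros);
  arma::rowvec db(4 * U, arma::fill::zeros);
  arma::mat dx(x.n_rows, x.n_cols, arma::fill::zeros);
  arma::mat dc(n, U, arma::fill::zeros);
  arma::mat dz(n, 4 * U);
  for (int t = len - 1; t >= 0; --t) {
    const arma::mat& i = K.slice(6 * t + 0);
    const arma::mat& f = K.slice(6 * t + 1);
    const arma::mat& g = K.slice(6 * t + 2);
    const arma::mat& o = K.slice(6 * t + 3);
    const arma::mat& tc = K.slice(6 * t + 4);
    dc += dh % o % (1.0 - tc % tc);
    dz.cols(0, U - 1) = (dc % g) % i % (1.0 - i);
    dz.cols(U, 2 * U - 1) = (dc % K.slice(6 * t + 5)) % f % (1.0 - f);
    dz.cols(2 * U, 3 * U - 1) = (dc % i) % (1.0 - g % g);
    dz.cols(3 * U, 4 * U - 1) = (dh % tc) % o % (1.0 - o);
    const arma::uvec rows = step_rows(t, n, len);
    dWx += x.rows(rows).t() * dz;
    dWh += (t > 0 ? arma::mat(K.slice(6 * (t - 1) + 3) %
                              K.slice(6 * (t - 1) + 4))
                  : arma::mat(n, U, arma::fill::zeros)).t() * dz;
    db += arma::sum(dz, 0);
    dx.rows(rows) = dz * Wx.t();
    dh = dz * Wh.t();
    dc %= f;
  }
  return List::create(_["dx"] = dx, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}
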