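// Profiled deviance of the polynomial growth-curve linear mixed model.
//
// Model: y_i = X_i beta + Z_i b_i + e_i, b_i ~ N(0, G), e_i ~ N(0, s2 / w_ij).
// G is parameterised as s2 * Lambda Lambda' with Lambda the lower-triangular
// relative Cholesky factor (log scale on the diagonal), so beta and s2 can be
// profiled out and the optimiser works on theta alone.
//
// Per subject, with Xt = sqrt(w) X_i etc., the Woodbury identity gives
//   X'V*^-1 X = Xt'Xt - a_x' M^-1 a_x,  M = I_q + L' Zt'Zt L,  a_x = L' Zt' Xt
// and log|V*_i| = log|M| - sum(log w_ij).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat lambda_from_theta(const Rcpp::NumericVector& theta, int q) {
  mat L(q, q, fill::zeros);
  int k = 0;
  for (int j = 0; j < q; ++j) {       // column-wise lower triangle
    for (int i = j; i < q; ++i) {
      double v = theta[k++];
      L(i, j) = (i == j) ? std::exp(v) : v;
    }
  }
  return L;
}

// [[Rcpp::export(name = ".lmm_profiled_cpp")]]
Rcpp::List lmm_profiled_cpp(Rcpp::NumericVector theta,
                            arma::mat X, arma::mat Z,
                            arma::vec y, arma::vec w,
                            arma::ivec starts, arma::ivec lens,
                            bool reml, bool want_components) {
  const int p = X.n_cols, q = Z.n_cols, m = starts.n_elem;
  const int n = X.n_rows;
  mat L = lambda_from_theta(theta, q);

  mat Sxx(p, p, fill::zeros);
  vec sxy(p, fill::zeros);
  double syy = 0.0, logdet = 0.0;

  for (int i = 0; i < m; ++i) {
    int a = starts[i], ni = lens[i];
    mat Xi = X.rows(a, a + ni - 1);
    mat Zi = Z.rows(a, a + ni - 1);
    vec yi = y.subvec(a, a + ni - 1);
    vec wi = w.subvec(a, a + ni - 1);
    vec sw = sqrt(wi);
    Xi.each_col() %= sw;
    Zi.each_col() %= sw;
    yi %= sw;

    mat ZtZ = Zi.t() * Zi;
    mat M = eye(q, q) + L.t() * ZtZ * L;
    mat R;
    if (!chol(R, M)) return Rcpp::List::create(Rcpp::Named("ok") = false);
    // a_x (q x p), a_y (q)
    mat ax = L.t() * (Zi.t() * Xi);
    vec ay = L.t() * (Zi.t() * yi);
    mat Rax = solve(trimatl(R.t()), ax);
    vec Ray = solve(trimatl(R.t()), ay);

    Sxx += Xi.t() * Xi - Rax.t() * Rax;
    sxy += Xi.t() * yi - Rax.t() * Ray;
    syy += dot(yi, yi) - dot(Ray, Ray);
    logdet += 2.0 * sum(log(R.diag())) - sum(log(wi));
  }

  mat Rx;
  if (!chol(Rx, symmatu(Sxx))) return Rcpp::List::create(Rcpp::Named("ok") = false);
  vec beta = solve(trimatu(Rx), solve(trimatl(Rx.t()), sxy));
  double rss = syy - dot(beta, sxy);
  if (rss < 0) rss = 0;           // exact-fit round-off guard
  double denom = reml ? (n - p) : n;
  double s2hat = rss / denom;
  double floor_ = 1e-10 * (syy / n + 1.0);
  double s2 = std::max(s2hat, floor_);
  double dev;
  if (!reml) {
    dev = n * std::log(2.0 * M_PI * s2) + logdet + rss / s2;
  } else {
    double logdet_xx = 2.0 * sum(log(Rx.diag()));
    dev = (n - p) * std::log(2.0 * M_PI * s2) + logdet + logdet_xx + rss / s2;
  }

  if (!want_components) {
    return Rcpp::List::create(Rcpp::Named("ok") = true,
                              Rcpp::Named("deviance") = dev);
  }
  mat Sxx_inv = inv_sympd(symmatu(Sxx));
  mat G = s2 * (L * L.t());
  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("deviance") = dev,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("sigma2") = s2,
    Rcpp::Named("sigma2_floored") = (s2hat < floor_),
    Rcpp::Named("G") = G,
    Rcpp::Named("Vbeta") = s2 * Sxx_inv,
    Rcpp::Named("Sxx") = symmatu(Sxx),
    Rcpp::Named("rss") = rss,
    Rcpp::Named("logdet") = logdet);
}
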