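// Gibbs sampler for the Gaussian variance-component model
//   y = X beta + u_g[genotype] + u_t[tank] + e
// with conjugate full conditionals: normal draws for beta and the random
// effect vectors, inverse-gamma draws for the three variance components.
// Uses R's RNG so chains are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// prior_shape / prior_rate: inverse-gamma hyperparameters per component,
// in the order (genotype, tank, residual).
// Returned draws: columns s2_g, s2_t, s2_e, then the p fixed effects.

// [[Rcpp::export]]
arma::mat gibbs_varcomp(const arma::vec& y, const arma::mat& X,
                        const arma::ivec& g, const arma::ivec& t,
                        int n_iter, int burn_in, int thin,
                        const arma::vec& prior_shape,
                        const arma::vec& prior_rate) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int qg = g.max() + 1;
  const int qt = t.max() + 1;

  arma::mat XtX = X.t() * X;
  arma::mat XtXinv = arma::inv_sympd(XtX);
  arma::mat Lb = arma::chol(XtXinv, "lower");

  arma::vec ng(qg, arma::fill::zeros), nt(qt, arma::fill::zeros);
  for (int i = 0; i < n; i++) { ng(g(i))++; nt(t(i))++; }

  const double vy = arma::var(y);
  double s2e = std::max(vy / 2.0, 1e-12);
  double s2g = std::max(vy / 4.0, 1e-12);
  double s2t = std::max(vy / 4.0, 1e-12);

  arma::vec ug(qg, arma::fill::zeros), ut(qt, arma::fill::zeros);
  arma::vec beta = XtXinv * (X.t() * y);
  arma::vec xb = X * beta;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat draws(n_keep, 3 + p);
  int k = 0;

  arma::vec r(n), z(p), sg(qg), st(qt);
  for (int iter = 1; iter <= n_iter; iter++) {
    // beta | rest ~ N((X'X)^-1 X'r, s2e (X'X)^-1)
    for (int i = 0; i < n; i++) r(i) = y(i) - ug(g(i)) - ut(t(i));
    arma::vec mb = XtXinv * (X.t() * r);
    for (int j = 0; j < p; j++) z(j) = R::norm_rand();
    beta = mb + std::sqrt(s2e) * (Lb * z);
    xb = X * beta;

    // genotype effects: independent normals (Z'Z diagonal)
    sg.zeros();
    for (int i = 0; i < n; i++) sg(g(i)) += y(i) - xb(i) - ut(t(i));
    for (int j = 0; j < qg; j++) {
      double prec = ng(j) / s2e + 1.0 / s2g;
      ug(j) = (sg(j) / s2e) / prec + R::norm_rand() / std::sqrt(prec);
    }

    // tank effects
    st.zeros();
    for (int i = 0; i < n; i++) st(t(i)) += y(i) - xb(i) - ug(g(i));
    for (int j = 0; j < qt; j++) {
      double prec = nt(j) / s2e + 1.0 / s2t;
      ut(j) = (st(j) / s2e) / prec + R::norm_rand() / std::sqrt(prec);
    }

    // variance components: scaled inverse-gamma full conditionals
    double sse = 0.0;
    for (int i = 0; i < n; i++) {
      double e = y(i) - xb(i) - ug(g(i)) - ut(t(i));
      sse += e * e;
    }
    s2e = 1.0 / R::rgamma(prior_shape(2) + n  / 2.0,
                          1.0 / (prior_rate(2) + sse / 2.0));
    s2g = 1.0 / R::rgamma(prior_shape(0) + qg / 2.0,
                          1.0 / (prior_rate(0) + arma::dot(ug, ug) / 2.0));
    s2t = 1.0 / R::rgamma(prior_shape(1) + qt / 2.0,
                          1.0 / (prior_rate(1) + arma::dot(ut, ut) / 2.0));

    if (iter > burn_in && (iter - burn_in) % thin == 0 && k < n_keep) {
      draws(k, 0) = s2g;
      draws(k, 1) = s2t;
      draws(k, 2) = s2e;
      for (int j = 0; j < p; j++) draws(k, 3 + j) = beta(j);
      k++;
    }
  }
  return draws;
}
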