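#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Plain IRLS for a Bernoulli GLM with logit link.  Used by the stacking
// learners, where many small logistic fits are scored inside the
// cross-validation loop; mirrors glm.fit's deviance-based stopping rule.
// [[Rcpp::export]]
Rcpp::List fast_logit_fit(const arma::mat& X, const arma::vec& y,
                          Rcpp::Nullable<Rcpp::NumericVector> start,
                          double epsilon, int maxit) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  if (start.isNotNull()) {
    beta = Rcpp::as<arma::vec>(start.get());
  }
  double dev = arma::datum::inf;
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, X.t() * Xw, X.t() * (w % z),
                          arma::solve_opts::no_approx);
    if (!ok) {
      Rcpp::stop("singular information matrix");
    }
    arma::vec eta_new = arma::clamp(X * beta_new, -30.0, 30.0);
    arma::vec mu_new = 1.0 / (1.0 + arma::exp(-eta_new));
    mu_new = arma::clamp(mu_new, 1e-12, 1.0 - 1e-12);
    double dev_new = -2.0 * arma::accu(y % arma::log(mu_new) +
                                       (1.0 - y) % arma::log(1.0 - mu_new));
    // step-halving safeguard as in glm.fit
    int halvings = 0;
    while (!std::isfinite(dev_new) ||
           (std::isfinite(dev) && dev_new > dev + 1e-8)) {
      if (++halvings > 25) break;
      beta_new = (beta + beta_new) / 2.0;
      eta_new = arma::clamp(X * beta_new, -30.0, 30.0);
      mu_new = arma::clamp(1.0 / (1.0 + arma::exp(-eta_new)),
                           1e-12, 1.0 - 1e-12);
      dev_new = -2.0 * arma::accu(y % arma::log(mu_new) +
                                  (1.0 - y) % arma::log(1.0 - mu_new));
    }
    beta = beta_new;
    if (std::isfinite(dev) &&
        std::abs(dev - dev_new) / (std::abs(dev_new) + 0.1) < epsilon) {
      dev = dev_new;
      converged = true;
      break;
    }
    dev = dev_new;
  }
  return Rcpp::List::create(Rcpp::Named("coef") = beta,
                            Rcpp::Named("deviance") = dev,
                            Rcpp::Named("converged") = converged);
}
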