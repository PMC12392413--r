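#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the 4-component normal-mixture marker-effect model
// y = mu + X beta + e, with component variances (0, 1e-4, 1e-3, 1e-2) x
// sigma_g2 and class-specific Dirichlet(1,1,1,1) mixing proportions.
// class_id is 1-based per SNP; ncat is the number of disjoint classes.
// Uses R's RNG so chains are reproducible under set.seed().
// [[Rcpp::export]]
List bayesr_gibbs_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::ivec& class_id, int ncat,
                      int burnin, int numit,
                      double nu, double scale_g, double scale_e) {
  const int n = X.n_rows, p = X.n_cols;
  const arma::vec gamma = {0.0, 1e-4, 1e-3, 1e-2};

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  double mu = arma::mean(y);
  arma::vec beta(p, arma::fill::zeros);
  arma::ivec comp(p, arma::fill::ones);          // start in the null class
  arma::mat pi(ncat, 4);
  pi.fill(0.25);
  double vy = arma::var(y);
  double sigma_e2 = vy / 2.0, sigma_g2 = vy / 2.0;
  arma::vec r = y - mu;                          // residual (beta = 0)

  // posterior accumulators
  arma::vec beta_sum(p, arma::fill::zeros), pip_sum(p, arma::fill::zeros);
  arma::mat pi_sum(ncat, 4, arma::fill::zeros);
  double mu_sum = 0, sg_sum = 0, se_sum = 0;
  int kept = 0;

  RNGScope scope;
  for (int it = 0; it < numit; ++it) {
    // intercept
    double radj = arma::mean(r) + mu;
    double mu_new = R::rnorm(radj, std::sqrt(sigma_e2 / n));
    r += mu - mu_new;
    mu = mu_new;

    // per-SNP component + effect
    for (int j = 0; j < p; ++j) {
      if (beta(j) != 0.0) r += X.col(j) * beta(j);
      double rhs = arma::dot(X.col(j), r);
      int c = class_id(j) - 1;
      double logl[4], uhat[4], lhs[4];
      logl[0] = std::log(pi(c, 0));
      double maxl = logl[0];
      for (int k = 1; k < 4; ++k) {
        double v = gamma(k) * sigma_g2;
        if (v <= 0.0) { logl[k] = -1e300; continue; }
        lhs[k] = xtx(j) + sigma_e2 / v;
        uhat[k] = rhs / lhs[k];
        logl[k] = std::log(pi(c, k))
          - 0.5 * std::log(v * xtx(j) / sigma_e2 + 1.0)
          + 0.5 * rhs * uhat[k] / sigma_e2;
        if (logl[k] > maxl) maxl = logl[k];
      }
      double cum[4], tot = 0;
      for (int k = 0; k < 4; ++k) {
        tot += std::exp(logl[k] - maxl);
        cum[k] = tot;
      }
      double u = R::runif(0.0, tot);
      int k = 0;
      while (k < 3 && u > cum[k]) ++k;
      comp(j) = k + 1;
      if (k == 0) {
        beta(j) = 0.0;
      } else {
        beta(j) = R::rnorm(uhat[k], std::sqrt(sigma_e2 / lhs[k]));
        r -= X.col(j) * beta(j);
      }
    }

    // mixing proportions: Dirichlet(1 + counts) per class
    arma::mat counts(ncat, 4, arma::fill::zeros);
    for (int j = 0; j < p; ++j) counts(class_id(j) - 1, comp(j) - 1) += 1.0;
    for (int c = 0; c < ncat; ++c) {
      double s = 0;
      arma::rowvec d(4);
      for (int k = 0; k < 4; ++k) {
        d(k) = R::rgamma(1.0 + counts(c, k), 1.0);
        s += d(k);
      }
      pi.row(c) = d / s;
    }

    // genetic variance: scaled-inverse-chi-square
    double ssg = 0; int nnz = 0;
    for (int j = 0; j < p; ++j) {
      if (comp(j) > 1) {
        ssg += beta(j) * beta(j) / gamma(comp(j) - 1);
        ++nnz;
      }
    }
    sigma_g2 = (nu * scale_g + ssg) / R::rchisq(nu + nnz);

    // residual variance
    sigma_e2 = (nu * scale_e + arma::dot(r, r)) / R::rchisq(nu + n);

    if (it >= burnin) {
      beta_sum += beta;
      for (int j = 0; j < p; ++j) if (comp(j) > 1) pip_sum(j) += 1.0;
      pi_sum += pi;
      mu_sum += mu; sg_sum += sigma_g2; se_sum += sigma_e2;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_sum / kept,
    _["pip"] = pip_sum / kept,
    _["pi"] = pi_sum / kept,
    _["mu"] = mu_sum / kept,
    _["sigma_g2"] = sg_sum / kept,
    _["sigma_e2"] = se_sum / kept,
    _["n_kept"] = kept);
}
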