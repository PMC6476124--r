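// Joint latent class likelihood kernel.
//
// Computes, for every subject i and class g, the log of
//   pi_ig * f(Y_i | g) * (event contribution)_ig
// where f is the multivariate-normal density of the link-transformed
// creatinine measurements (random intercept + slope, residual sigma) already
// including the link log-Jacobians, and the event contribution is the
// class-specific Weibull proportional-hazards term with right censoring and
// optional delayed entry. Mixing over classes (log-sum-exp) happens in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_joint_contrib(const arma::vec& tmeas,   // concatenated measurement times
                            const arma::vec& h,       // transformed measurements
                            const arma::ivec& first,  // 0-based start index per subject
                            const arma::ivec& ni,     // measurements per subject
                            const arma::vec& logjac,  // per-subject summed log-Jacobians
                            const arma::mat& beta,    // G x 3 fixed effects
                            const arma::mat& B,       // 2 x 2 random-effect covariance
                            const arma::vec& wg2,     // G variance multipliers for B
                            const double sigma2,      // residual variance
                            const arma::mat& logpi,   // n x G log membership probabilities
                            const arma::vec& entry,   // delayed-entry times (0 = none)
                            const arma::vec& tev,     // event/censoring times
                            const arma::vec& dev,     // event indicators
                            const arma::vec& lp,      // x_s' delta per subject
                            const arma::mat& zeta,    // G x 2 Weibull parameters
                            const bool use_event) {
  const int n = first.n_elem;
  const int G = beta.n_rows;
  const double LOG2PI = std::log(2.0 * M_PI);
  arma::mat out(n, G);
  const bool common_cov = arma::all(arma::abs(wg2 - wg2(0)) < 1e-300);

  for (int i = 0; i < n; ++i) {
    const int m = ni(i);
    const arma::vec ti = tmeas.subvec(first(i), first(i) + m - 1);
    const arma::vec hi = h.subvec(first(i), first(i) + m - 1);
    arma::mat Z(m, 2);
    Z.col(0).ones();
    Z.col(1) = ti;

    arma::mat L;
    double ldet = 0.0;
    if (common_cov) {
      arma::mat V = wg2(0) * (Z * B * Z.t());
      V.diag() += sigma2;
      if (!arma::chol(L, V, "lower")) {
        V.diag() += 1e-8;
        arma::chol(L, V, "lower");
      }
      ldet = 2.0 * arma::sum(arma::log(L.diag()));
    }

    for (int g = 0; g < G; ++g) {
      if (!common_cov) {
        arma::mat V = wg2(g) * (Z * B * Z.t());
        V.diag() += sigma2;
        if (!arma::chol(L, V, "lower")) {
          V.diag() += 1e-8;
          arma::chol(L, V, "lower");
        }
        ldet = 2.0 * arma::sum(arma::log(L.diag()));
      }
      arma::vec mu = beta(g, 0) + beta(g, 1) * ti + beta(g, 2) * arma::square(ti);
      arma::vec u = arma::solve(arma::trimatl(L), hi - mu);
      double ll = -0.5 * (m * LOG2PI + ldet + arma::dot(u, u)) + logjac(i);

      if (use_event) {
        const double z1 = zeta(g, 0), z2 = zeta(g, 1);
        const double elp = std::exp(lp(i));
        ll -= std::pow(z1 * tev(i), z2) * elp;
        if (entry(i) > 0.0) ll += std::pow(z1 * entry(i), z2) * elp;
        if (dev(i) > 0.5) {
          ll += std::log(z1) + std::log(z2) + (z2 - 1.0) * std::log(z1 * tev(i)) + lp(i);
        }
      }
      out(i, g) = logpi(i, g) + ll;
    }
  }
  return out;
}
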