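// Hot loops of the Gibbs sampler: elliptical slice sampling of the latent
// multivariate-normal logits (one subject at a time, Bernoulli likelihood
// over observed cells only) and the discrete Gibbs scan over the variable
// selection indicators. R-level RNG is used throughout so runs are
// reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// y * z - log(1 + exp(z)), overflow-safe
static inline double cell_loglik(double y, double z) {
  double l1p = (z > 35.0) ? z : ((z < -35.0) ? std::exp(z) : std::log1p(std::exp(z)));
  return y * z - l1p;
}

static inline double row_loglik(const arma::mat& Y, const arma::umat& obs,
                                const arma::vec& z, int i) {
  double ll = 0.0;
  for (arma::uword j = 0; j < z.n_elem; ++j)
    if (obs(i, j)) ll += cell_loglik(Y(i, j), z(j));
  return ll;
}

// One elliptical-slice-sampling sweep over all subjects.
// Z, Mu: n x d current logits and their prior means; Lchol: lower Cholesky
// factor of the latent covariance; Y: outcomes with arbitrary values in
// masked cells; obs: 0/1 observation mask.
// [[Rcpp::export(name = ".ess_update_z")]]
arma::mat ess_update_z(const arma::mat& Z, const arma::mat& Mu,
                       const arma::mat& Lchol, const arma::mat& Y,
                       const arma::umat& obs) {
  const int n = Z.n_rows, d = Z.n_cols;
  arma::mat Znew = Z;
  arma::vec eps(d), nu(d), z(d), zc(d), zp(d), mu(d);
  for (int i = 0; i < n; ++i) {
    mu = Mu.row(i).t();
    z = Znew.row(i).t();
    for (int j = 0; j < d; ++j) eps(j) = R::norm_rand();
    nu = Lchol * eps;
    double logy = row_loglik(Y, obs, z, i) + std::log(R::unif_rand());
    double theta = R::unif_rand() * 2.0 * M_PI;
    double lo = theta - 2.0 * M_PI, hi = theta;
    zc = z - mu;
    for (int it = 0; it < 200; ++it) {
      zp = mu + zc * std::cos(theta) + nu * std::sin(theta);
      if (row_loglik(Y, obs, zp, i) > logy) { Znew.row(i) = zp.t(); break; }
      if (theta < 0.0) lo = theta; else hi = theta;
      theta = lo + R::unif_rand() * (hi - lo);
      if (hi - lo < 1e-12) break; // numerically closed bracket: keep current z
    }
  }
  return Znew;
}

// Collapsed Gibbs update of the inclusion indicators: for each (p, j) the
// coefficient beta[p, j] is integrated out analytically under its
// N(0, sigma2_beta) prior (the latent-logit regression is linear-Gaussian
// given z), the indicator is drawn from its marginal conditional odds, and
// the coefficient is then redrawn from its exact conditional — its
// posterior when included, its prior when excluded. Joint draws of
// (I, beta) from the bivariate conditional avoid the poor mixing of
// updating the indicator given a prior-drifting excluded coefficient.
// R: n x d regression target (latent logits minus the random effect),
// M: current mean X1 * xi, X1: n x (p+1) design with intercept, beta:
// (p+1) x d, I: p x d indicators, psi: p x d inclusion probabilities,
// P: inverse of the latent covariance, s2: coefficient prior variance.
// Returns updated I, beta and M.
// [[Rcpp::export(name = ".gibbs_indicators")]]
List gibbs_indicators(const arma::mat& R, arma::mat M, const arma::mat& X1,
                      arma::mat beta, arma::imat I,
                      const arma::mat& psi, const arma::mat& P,
                      const double s2) {
  const int p = I.n_rows, d = I.n_cols;
  for (int pp = 0; pp < p; ++pp) {
    arma::vec xcol = X1.col(pp + 1);
    double xx = arma::dot(xcol, xcol);
    for (int j = 0; j < d; ++j) {
      if (I(pp, j) == 1) M.col(j) -= beta(pp + 1, j) * xcol; // remove the term
      arma::vec u = (R - M) * P.col(j);
      double a = arma::dot(xcol, u);          // d loglik / d beta at 0
      double c = P(j, j) * xx;                // curvature
      double v = 1.0 / (c + 1.0 / s2);        // conditional posterior variance
      double delta = 0.5 * a * a * v + 0.5 * std::log(v / s2);
      double logodds = std::log(psi(pp, j)) - std::log1p(-psi(pp, j)) + delta;
      double pr = 1.0 / (1.0 + std::exp(-logodds));
      int newI = (R::unif_rand() < pr) ? 1 : 0;
      I(pp, j) = newI;
      if (newI == 1) {
        double bnew = a * v + std::sqrt(v) * R::norm_rand();
        beta(pp + 1, j) = bnew;
        M.col(j) += bnew * xcol;
      } else {
        beta(pp + 1, j) = std::sqrt(s2) * R::norm_rand();
      }
    }
  }
  return List::create(Named("I") = I, Named("beta") = beta, Named("M") = M);
}
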