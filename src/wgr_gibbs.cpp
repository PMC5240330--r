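// Single-site Gibbs sampler for Bayesian whole-genome regression with a
// point-mass/slab mixture prior on marker effects, optionally extended with
// an imputation-residual block for single-step analyses.
//
// family 0 = common marker-effect variance (normal slab);
// family 1 = locus-specific variances (t slab via scaled-inv-chi-square).
//
// All randomness comes from R's RNG so set.seed() on the R side gives
// bitwise-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List wgr_gibbs(const arma::vec& y, const arma::mat& X, const arma::mat& M,
               int family, double pi0, bool estimate_pi,
               double nu_alpha, double S_alpha2,
               double nu_e, double S_e2, double nu_g, double S_g2,
               bool fix_sigma_e2, bool fix_sigma_a2, bool fix_sigma_g2,
               double sigma_e2, double sigma_a2, double sigma_g2,
               const arma::mat& Cinv, const arma::ivec& eps_of_record,
               int n_iter, int burn_in, int thin, bool keep_alpha)
{
  const int n = y.n_elem;
  const int p = M.n_cols;
  const int nb = X.n_cols;
  const int n_eps = Cinv.n_rows;

  arma::vec beta(nb, arma::fill::zeros);
  arma::vec alpha(p, arma::fill::zeros);
  arma::vec locus_var(p);
  locus_var.fill(sigma_a2);
  arma::vec eps(n_eps, arma::fill::zeros);
  arma::vec e = y;          // residual: y - X beta - M alpha - Z_n eps
  double pi_cur = pi0;

  // column norms
  arma::vec cnorm(p);
  for (int j = 0; j < p; ++j) cnorm[j] = arma::dot(M.col(j), M.col(j));

  // fixed-effect factor
  arma::mat XtX = X.t() * X;
  arma::mat Rx = arma::chol(XtX);

  // eps bookkeeping
  arma::vec eps_cnt(std::max(n_eps, 1), arma::fill::zeros);
  for (int r = 0; r < n; ++r)
    if (eps_of_record[r] >= 0) eps_cnt[eps_of_record[r]] += 1.0;
  arma::mat Reps, Omega_inv, Ls;
  bool eps_factor_fresh = false;
  const bool eps_factor_const = fix_sigma_e2 && fix_sigma_g2;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::vec alpha_sum(p, arma::fill::zeros);
  arma::vec inc_sum(p, arma::fill::zeros);
  arma::vec eps_sum(std::max(n_eps, 1), arma::fill::zeros);
  arma::mat beta_chain(n_keep, nb);
  arma::vec se2_chain(n_keep), sa2_chain(n_keep), sg2_chain(n_keep),
            pi_chain(n_keep), varg_chain(n_keep);
  arma::mat alpha_draws;
  if (keep_alpha) alpha_draws.set_size(n_keep, p);

  int k = 0;
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects: flat prior, joint draw
    arma::vec w = e + X * beta;
    arma::vec bhat = arma::solve(XtX, X.t() * w);
    arma::vec zb(nb);
    for (int i = 0; i < nb; ++i) zb[i] = R::rnorm(0.0, 1.0);
    beta = bhat + arma::solve(arma::trimatu(Rx), zb) * std::sqrt(sigma_e2);
    e = w - X * beta;

    // marker effects
    int m_in = 0;
    double ssq_alpha = 0.0;
    for (int j = 0; j < p; ++j) {
      if (alpha[j] != 0.0) e += M.col(j) * alpha[j];
      const double c = cnorm[j];
      if (c <= 0.0) { alpha[j] = 0.0; continue; }
      const double vj = (family == 1) ? locus_var[j] : sigma_a2;
      const double lambda = sigma_e2 / vj;
      const double rhs = arma::dot(M.col(j), e);
      bool incl = true;
      if (pi_cur > 0.0) {
        const double logbf = 0.5 * (std::log(lambda / (c + lambda)) +
                                    rhs * rhs / (sigma_e2 * (c + lambda)));
        // P(delta=1) = (1-pi) / ((1-pi) + pi exp(-logbf)), computed stably
        const double lo = std::log1p(-pi_cur) + logbf;
        const double l0 = std::log(pi_cur);
        const double pin = 1.0 / (1.0 + std::exp(l0 - lo));
        incl = R::runif(0.0, 1.0) < pin;
      }
      if (incl) {
        const double mean = rhs / (c + lambda);
        alpha[j] = R::rnorm(mean, std::sqrt(sigma_e2 / (c + lambda)));
        e -= M.col(j) * alpha[j];
        ++m_in;
        if (family == 0) ssq_alpha += alpha[j] * alpha[j];
      } else {
        alpha[j] = 0.0;
      }
      if (family == 1) {
        // locus variance: full conditional when included, prior when not
        if (incl)
          locus_var[j] = (nu_alpha * S_alpha2 + alpha[j] * alpha[j]) /
                         R::rchisq(nu_alpha + 1.0);
        else
          locus_var[j] = (nu_alpha * S_alpha2) / R::rchisq(nu_alpha);
      }
    }
    if (family == 0 && !fix_sigma_a2)
      sigma_a2 = (nu_alpha * S_alpha2 + ssq_alpha) / R::rchisq(nu_alpha + m_in);
    if (estimate_pi)
      pi_cur = R::rbeta(p - m_in + 1.0, m_in + 1.0);

    // imputation residuals: one block draw
    if (n_eps > 0) {
      for (int r = 0; r < n; ++r)
        if (eps_of_record[r] >= 0) e[r] += eps[eps_of_record[r]];
      arma::vec rhs(n_eps, arma::fill::zeros);
      for (int r = 0; r < n; ++r)
        if (eps_of_record[r] >= 0) rhs[eps_of_record[r]] += e[r];
      rhs /= sigma_e2;
      if (!eps_factor_const || !eps_factor_fresh) {
        arma::mat Omega = Cinv / sigma_g2;
        Omega.diag() += eps_cnt.head(n_eps) / sigma_e2;
        if (eps_factor_const) {
          // constant precision: cache its inverse and a sampling factor so
          // each draw is two matrix-vector products
          Omega_inv = arma::inv_sympd(Omega);
          Ls = arma::chol(Omega_inv, "lower");
        } else {
          Reps = arma::chol(Omega);
        }
        eps_factor_fresh = true;
      }
      arma::vec ze(n_eps);
      for (int i = 0; i < n_eps; ++i) ze[i] = R::rnorm(0.0, 1.0);
      if (eps_factor_const) {
        eps = Omega_inv * rhs + Ls * ze;
      } else {
        arma::vec mean = arma::solve(arma::trimatu(Reps),
                          arma::solve(arma::trimatl(Reps.t()), rhs),
                          arma::solve_opts::fast);
        eps = mean + arma::solve(arma::trimatu(Reps), ze,
                                 arma::solve_opts::fast);
      }
      for (int r = 0; r < n; ++r)
        if (eps_of_record[r] >= 0) e[r] -= eps[eps_of_record[r]];
      if (!fix_sigma_g2) {
        const double quad = arma::dot(eps, Cinv * eps);
        sigma_g2 = (nu_g * S_g2 + quad) / R::rchisq(nu_g + n_eps);
        eps_factor_fresh = false;
      }
    }

    if (!fix_sigma_e2) {
      sigma_e2 = (nu_e * S_e2 + arma::dot(e, e)) / R::rchisq(nu_e + n);
      eps_factor_fresh = eps_factor_const;
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      alpha_sum += alpha;
      for (int j = 0; j < p; ++j) if (alpha[j] != 0.0) inc_sum[j] += 1.0;
      if (n_eps > 0) eps_sum.head(n_eps) += eps;
      beta_chain.row(k) = beta.t();
      se2_chain[k] = sigma_e2;
      sa2_chain[k] = (family == 1) ? arma::mean(locus_var) : sigma_a2;
      sg2_chain[k] = sigma_g2;
      pi_chain[k] = pi_cur;
      arma::vec g = M * alpha;
      varg_chain[k] = arma::var(g);
      if (keep_alpha) alpha_draws.row(k) = alpha.t();
      ++k;
    }
  }

  List out = List::create(
    _["alpha_mean"] = alpha_sum / k,
    _["inclusion_prob"] = inc_sum / k,
    _["eps_mean"] = (n_eps > 0) ? arma::vec(eps_sum.head(n_eps) / k)
                                : arma::vec(),
    _["beta_chain"] = beta_chain.rows(0, k - 1),
    _["sigma_e2_chain"] = se2_chain.head(k),
    _["sigma_a2_chain"] = sa2_chain.head(k),
    _["sigma_g2_chain"] = sg2_chain.head(k),
    _["pi_chain"] = pi_chain.head(k),
    _["varg_chain"] = varg_chain.head(k),
    _["n_kept"] = k);
  if (keep_alpha) out["alpha_draws"] = alpha_draws.rows(0, k - 1);
  return out;
}
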