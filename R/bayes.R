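## Bayesian whole-genome regression (mixture priors on marker effects) for
## genotyped animals, and the single-step extension that adds imputed
## genotype covariates, an imputation-residual block and the genotyped-group
## mean shift.

#' Prior specification for marker effects
#'
#' Marker effects follow a mixture of a point mass at zero (probability `pi`)
#' and a slab: a normal with one common variance (`family = "C"`) or a
#' t-distribution via locus-specific scaled-inverse-chi-square variances
#' (`family = "B"`). With `estimate_pi = TRUE`, `pi` is an initial value and
#' is sampled from its Beta full conditional under a uniform prior. `pi = 0`
#' with family C is ridge regression / GBLUP; family B with `pi = 0` is the
#' t-prior model.
#'
#' @param family `"C"` (common variance) or `"B"` (locus variances).
#' @param pi prior probability of a zero effect, in `[0, 1)`.
#' @param estimate_pi sample `pi`.
#' @param nu_alpha slab degrees of freedom (default 4.2).
#' @param S_alpha2 slab scale; `NULL` = derive at fit time from the prior
#'   heritability, `var(y)` and the marker heterozygosity sum.
#' @return a list of class `"prior_spec"`.
#' @export
prior_spec <- function(family = c("C", "B"), pi = 0.95, estimate_pi = FALSE,
                       nu_alpha = 4.2, S_alpha2 = NULL) {
  family <- match.arg(family)
  if (pi < 0 || pi >= 1) stop("pi must be in [0, 1): pi = 1 excludes all effects a priori")
  structure(list(family = family, pi = pi, estimate_pi = estimate_pi,
                 nu_alpha = nu_alpha, S_alpha2 = S_alpha2),
            class = "prior_spec")
}

#' The pi grid used to pick a prior by cross-validation
#'
#' `0.9999, 0.999, 0.995, 0.99, 0.98`, then 0.95 down to 0.60 in steps of
#' 0.05.
#'
#' @return numeric vector of pi values.
#' @export
pi_grid <- function() {
  c(0.9999, 0.999, 0.995, 0.99, 0.98, seq(0.95, 0.60, by = -0.05))
}

## derive slab scale and variance defaults
slab_scale <- function(prior, vc, var_y, het_sum) {
  if (!is.null(prior$S_alpha2)) return(prior$S_alpha2)
  h2 <- if (!is.null(vc$sigma_g2) && !is.null(vc$sigma_e2)) {
    vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2)
  } else vc$prior_h2
  frac_in <- max(1 - prior$pi, 1e-4)
  h2 * var_y / (frac_in * het_sum) * (prior$nu_alpha - 2) / prior$nu_alpha
}

as_posterior <- function(raw, method, ebv, mu_g_chain = NULL) {
  out <- list(
    method = method,
    alpha_mean = drop(raw$alpha_mean),
    inclusion_prob = drop(raw$inclusion_prob),
    mu = mean(raw$beta_chain[, 1L]),
    mu_chain = raw$beta_chain[, 1L],
    mu_g_chain = mu_g_chain,
    mu_g = if (!is.null(mu_g_chain)) mean(mu_g_chain) else NULL,
    pi_chain = drop(raw$pi_chain),
    sigma_e2_chain = drop(raw$sigma_e2_chain),
    sigma_a2_chain = drop(raw$sigma_a2_chain),
    sigma_g2_chain = drop(raw$sigma_g2_chain),
    varg_chain = drop(raw$varg_chain),
    h2_chain = drop(raw$varg_chain) /
      (drop(raw$varg_chain) + drop(raw$sigma_e2_chain)),
    eps_mean = if (length(raw$eps_mean)) drop(raw$eps_mean) else NULL,
    ebv = ebv,
    n_kept = raw$n_kept,
    alpha_draws = raw$alpha_draws
  )
  class(out) <- "ssgp_posterior"
  out
}

#' @export
print.ssgp_posterior <- function(x, ...) {
  cat(sprintf("%s posterior: %d kept draws, %d markers, mean pi = %.4f\n",
              x$method, x$n_kept, length(x$alpha_mean), mean(x$pi_chain)))
  invisible(x)
}

#' Bayesian whole-genome regression on genotyped animals
#'
#' Gibbs sampler for `y = 1 mu + M_g alpha + e` with a flat prior on `mu`, a
#' point-mass/slab mixture on each marker effect (see [prior_spec()]) and a
#' scaled-inverse-chi-square prior on the residual variance. Each locus is
#' updated single-site: the inclusion indicator from its marginal Bayes
#' factor against the point mass, then the effect from its normal full
#' conditional. Family B samples a variance per locus, family C one common
#' variance, and `estimate_pi` adds a Beta draw for `pi`.
#'
#' With `vc$fixed = TRUE` the residual variance (and, for family C, the
#' marker-effect variance) are held at their supplied values — the setting in
#' which the `pi = 0` family-C posterior mean equals ridge regression.
#'
#' @param phenos data frame `id, value` for (a subset of) the genotyped
#'   animals; rows of `M_g` are matched by ID.
#' @param M_g complete genotype matrix of genotyped animals (QC-filtered and
#'   mean-imputed).
#' @param prior a [prior_spec()].
#' @param vc [variance_components()].
#' @param chain [mcmc_settings()].
#' @param sigma_alpha2 optional explicit marker-effect variance (fixed value
#'   when `vc$fixed`, initial value otherwise); default derived from the
#'   prior heritability.
#' @param keep_draws retain the thinned marker-effect draws (needed by
#'   [window_variance()]).
#' @return an object of class `"ssgp_posterior"`: posterior-mean effects,
#'   inclusion probabilities, variance/pi chains, and `ebv` for every row of
#'   `M_g` (genotyped animals only).
#' @export
fit_bayes_regression <- function(phenos, M_g, prior, vc, chain = mcmc_settings(),
                                 sigma_alpha2 = NULL, keep_draws = FALSE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(vc, "varcomp"),
            inherits(chain, "mcmc_settings"))
  if (anyNA(M_g)) stop("genotypes must be imputed before fitting")
  pos <- match(as.character(phenos$id), rownames(M_g))
  if (anyNA(pos)) stop("phenotyped animal(s) without genotypes")
  y <- phenos$value
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  M <- M_g[pos, , drop = FALSE]
  vc <- fill_vc_scales(vc, var(y))
  q <- colMeans(M_g) / 2
  het_sum <- sum(2 * q * (1 - q))
  S_a2 <- slab_scale(prior, vc, var(y), het_sum)
  sa2_init <- if (!is.null(sigma_alpha2)) sigma_alpha2 else
    S_a2 * prior$nu_alpha / (prior$nu_alpha - 2)
  if (!is.null(sigma_alpha2)) S_a2 <- sigma_alpha2 * (prior$nu_alpha - 2) / prior$nu_alpha
  set.seed(chain$seed)
  raw <- wgr_gibbs(
    y = y, X = matrix(1, length(y), 1L), M = M,
    family = if (prior$family == "B") 1L else 0L,
    pi0 = prior$pi, estimate_pi = prior$estimate_pi,
    nu_alpha = prior$nu_alpha, S_alpha2 = S_a2,
    nu_e = vc$nu_e, S_e2 = vc$S_e2, nu_g = vc$nu_g, S_g2 = vc$S_g2,
    fix_sigma_e2 = vc$fixed,
    fix_sigma_a2 = vc$fixed && prior$family == "C",
    fix_sigma_g2 = TRUE,
    sigma_e2 = vc$sigma_e2, sigma_a2 = sa2_init, sigma_g2 = vc$sigma_g2,
    Cinv = matrix(0, 0L, 0L), eps_of_record = rep(-1L, length(y)),
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin,
    keep_alpha = keep_draws
  )
  ebv <- setNames(drop(M_g %*% raw$alpha_mean), rownames(M_g))
  label <- paste0("Bayes", prior$family,
                  if (prior$estimate_pi) "-pi" else sprintf("(pi=%g)", prior$pi))
  as_posterior(raw, label, ebv)
}

#' Assemble the single-step regression design
#'
#' Builds the pieces of the single-step marker model: imputed covariates
#' `M_hat_n = A_ng A_gg^-1 M_g` stacked over `M_g`, the genotyped-group
#' covariate `-[A_ng A_gg^-1 1; 1]` (the `mu_g` column of the fixed-effect
#' design), and the imputation-residual covariance
#' `C = A_nn - A_ng A_gg^-1 A_gn`. When every animal is genotyped the
#' residual block is empty and the group covariate is -1 for all rows.
#'
#' @param partition an [partition_nrm()] object.
#' @param M_g genotype matrix of the genotyped animals.
#' @return an object of class `"ssbr_design"`: `M` (stacked covariates, rows
#'   ordered non-genotyped then genotyped), `x_mu_g`, `epsilon_cov`, `ids`,
#'   `genotyped` (logical per row), `m_means` (genotyped column means).
#' @export
build_ssbr_design <- function(partition, M_g) {
  stopifnot(inherits(partition, "nrm_partition"))
  M_g <- M_g[partition$genotyped_ids, , drop = FALSE]
  n_n <- length(partition$nongenotyped_ids)
  if (n_n > 0L) {
    M_hat <- impute_nongenotyped(partition, M_g)
    P <- chol_solve(partition$A_gg, partition$A_gn, "A_gg")
    C <- partition$A_nn - partition$A_ng %*% P
    C <- (C + t(C)) / 2
  } else {
    M_hat <- M_g[0L, , drop = FALSE]
    C <- matrix(0, 0L, 0L)
  }
  ids <- c(partition$nongenotyped_ids, partition$genotyped_ids)
  out <- list(M = rbind(M_hat, M_g),
              x_mu_g = mu_g_covariate(partition),
              epsilon_cov = C,
              ids = ids,
              genotyped = setNames(c(rep(FALSE, n_n),
                                     rep(TRUE, length(partition$genotyped_ids))), ids),
              m_means = colMeans(M_g))
  rownames(out$M) <- ids
  class(out) <- "ssbr_design"
  out
}

#' Single-step Bayesian regression
#'
#' Extends [fit_bayes_regression()] to phenotypes on genotyped and
#' non-genotyped animals:
#' `y = X beta + Z M alpha + Z_n epsilon + e`, with flat priors on
#' `beta = (mu, mu_g)`, the mixture prior on `alpha`, and
#' `epsilon ~ N(0, (A_nn - A_ng A_gg^-1 A_gn) sigma_g2)` drawn as one block
#' per iteration from a Cholesky factorization (cached when variances are
#' fixed); `sigma_g2` is updated from the residual quadratic form.
#'
#' EBVs follow the single-step convention: `M_g alpha` for genotyped animals,
#' `M_hat_n alpha + epsilon` for non-genotyped ones; the genotyped-group
#' shift `mu_g` is reported separately and not folded into the EBV ranking
#' (validation animals are genotyped, so a common shift cancels in
#' correlations).
#'
#' @param phenos data frame `id, value` over training animals, genotyped or
#'   not.
#' @param design an [build_ssbr_design()] object.
#' @inheritParams fit_bayes_regression
#' @return an `"ssgp_posterior"` with `ebv` over all animals in the design
#'   and the `mu_g` chain.
#' @export
fit_ssbr <- function(phenos, design, prior, vc, chain = mcmc_settings(),
                     sigma_alpha2 = NULL, keep_draws = FALSE) {
  stopifnot(inherits(design, "ssbr_design"), inherits(prior, "prior_spec"))
  pos <- match(as.character(phenos$id), design$ids)
  if (anyNA(pos)) stop("phenotyped animal(s) missing from the design")
  y <- phenos$value
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  vc <- fill_vc_scales(vc, var(y))
  n_n <- sum(!design$genotyped)
  eps_of_record <- rep(-1L, length(y))
  is_non <- pos <= n_n
  eps_of_record[is_non] <- pos[is_non] - 1L  # 0-based into non-genotyped block
  Cinv <- if (n_n > 0L) chol_solve(design$epsilon_cov, diag(n_n), "epsilon_cov")
          else matrix(0, 0L, 0L)
  ## with no non-genotyped animals the group covariate is -1 everywhere,
  ## confounded with the intercept: drop it (plain-regression reduction)
  X <- if (n_n > 0L) cbind(1, design$x_mu_g[pos]) else matrix(1, length(y), 1L)
  q <- design$m_means / 2
  het_sum <- sum(2 * q * (1 - q))
  S_a2 <- slab_scale(prior, vc, var(y), het_sum)
  sa2_init <- if (!is.null(sigma_alpha2)) sigma_alpha2 else
    S_a2 * prior$nu_alpha / (prior$nu_alpha - 2)
  if (!is.null(sigma_alpha2)) S_a2 <- sigma_alpha2 * (prior$nu_alpha - 2) / prior$nu_alpha
  set.seed(chain$seed)
  raw <- wgr_gibbs(
    y = y, X = X, M = design$M[pos, , drop = FALSE],
    family = if (prior$family == "B") 1L else 0L,
    pi0 = prior$pi, estimate_pi = prior$estimate_pi,
    nu_alpha = prior$nu_alpha, S_alpha2 = S_a2,
    nu_e = vc$nu_e, S_e2 = vc$S_e2, nu_g = vc$nu_g, S_g2 = vc$S_g2,
    fix_sigma_e2 = vc$fixed,
    fix_sigma_a2 = vc$fixed && prior$family == "C",
    fix_sigma_g2 = vc$fixed,
    sigma_e2 = vc$sigma_e2, sigma_a2 = sa2_init, sigma_g2 = vc$sigma_g2,
    Cinv = Cinv, eps_of_record = eps_of_record,
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin,
    keep_alpha = keep_draws
  )
  ebv <- drop(design$M %*% raw$alpha_mean)
  if (n_n > 0L) ebv[seq_len(n_n)] <- ebv[seq_len(n_n)] + raw$eps_mean
  ebv <- setNames(ebv, design$ids)
  label <- paste0("SSBR-", prior$family,
                  if (prior$estimate_pi) "-pi" else sprintf("(pi=%g)", prior$pi))
  as_posterior(raw, label, ebv,
               mu_g_chain = if (ncol(X) > 1L) raw$beta_chain[, 2L])
}

#' Direct solution of the single-step regression at pi = 0
#'
#' For family C with `pi = 0` and fixed variances the posterior mean of
#' `(beta, alpha, epsilon)` is the solution of a ridge-penalized least-squares
#' system; this closed form is the deterministic counterpart of [fit_ssbr()]
#' and, after the marker-mean shift `x_mu_g * (m_bar' alpha_hat)`, is exactly
#' the single-step GBLUP solution computed from the unscaled centered G with
#' the genotyped-group covariate in the fixed effects.
#'
#' @inheritParams fit_ssbr
#' @param sigma_alpha2 marker-effect variance; typically
#'   `sigma_g2 / sum(2 q (1 - q))`.
#' @return list with `beta` (`mu`, `mu_g`), `alpha`, `eps`, `ebv` (single-step
#'   convention), `gamma` (the marker-mean contrast `m_bar' alpha`), and
#'   `ebv_h_scale` (`ebv + x_mu_g * gamma`, the H-matrix scale).
#' @export
solve_ssbr_direct <- function(phenos, design, vc, sigma_alpha2) {
  stopifnot(inherits(design, "ssbr_design"))
  if (!vc$fixed) stop("direct solve requires fixed variance components")
  pos <- match(as.character(phenos$id), design$ids)
  if (anyNA(pos)) stop("phenotyped animal(s) missing from the design")
  y <- phenos$value
  n_n <- sum(!design$genotyped)
  p <- ncol(design$M)
  X <- if (n_n > 0L) cbind(1, design$x_mu_g[pos]) else matrix(1, length(y), 1L)
  Mrec <- design$M[pos, , drop = FALSE]
  Zn <- matrix(0, length(y), n_n)
  is_non <- pos <= n_n
  Zn[cbind(which(is_non), pos[is_non])] <- 1
  W <- cbind(X, Mrec, Zn)
  nb <- ncol(X)
  P <- matrix(0, nb + p + n_n, nb + p + n_n)
  P[nb + seq_len(p), nb + seq_len(p)] <- diag(vc$sigma_e2 / sigma_alpha2, p)
  if (n_n > 0L) {
    Cinv <- chol_solve(design$epsilon_cov, diag(n_n), "epsilon_cov")
    P[nb + p + seq_len(n_n), nb + p + seq_len(n_n)] <- Cinv * vc$sigma_e2 / vc$sigma_g2
  }
  sol <- solve(crossprod(W) + P, crossprod(W, y))
  beta <- sol[seq_len(nb)]
  alpha <- sol[nb + seq_len(p)]
  eps <- if (n_n > 0L) sol[nb + p + seq_len(n_n)] else numeric(0)
  ebv <- drop(design$M %*% alpha)
  if (n_n > 0L) ebv[seq_len(n_n)] <- ebv[seq_len(n_n)] + eps
  ebv <- setNames(ebv, design$ids)
  gamma <- sum(design$m_means * alpha)
  list(beta = setNames(beta, c("mu", "mu_g")[seq_len(nb)]),
       alpha = alpha, eps = eps, ebv = ebv, gamma = gamma,
       ebv_h_scale = ebv + design$x_mu_g * gamma)
}

#' Summarize retained MCMC draws
#'
#' Generic chain summary: retains draws after `burn_in` at spacing `thin`,
#' then reports means, standard deviations and (for effect chains) the
#' fraction of nonzero draws.
#'
#' @param draws numeric vector or matrix (iterations in rows).
#' @param burn_in draws to discard from the front.
#' @param thin keep every `thin`-th retained draw.
#' @return list with `mean`, `sd`, `inclusion_prob`, `n_kept`.
#' @export
summarize_posterior <- function(draws, burn_in = 0L, thin = 1L) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  if (burn_in >= n) stop("burn_in leaves no retained draws")
  keep <- seq(burn_in + 1L, n, by = thin)
  kept <- draws[keep, , drop = FALSE]
  list(mean = colMeans(kept),
       sd = apply(kept, 2L, sd),
       inclusion_prob = colMeans(kept != 0),
       n_kept = length(keep))
}
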