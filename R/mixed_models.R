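## Linear mixed-model machinery: Henderson systems and GLS solves, pedigree
## BLUP, the single-step H matrix, and Gibbs-based variance estimation in the
## eigenspace of the relationship factor.

#' Variance components and their hyperpriors
#'
#' Holds the additive genetic and residual variances, either fixed (known) or
#' to be estimated by Gibbs sampling under scaled-inverse-chi-square priors
#' `nu * S2 / chisq(nu)`. When scales are not supplied they are derived at
#' fit time from a prior heritability and the phenotypic variance so that the
#' prior means match `prior_h2 * var(y)` and `(1 - prior_h2) * var(y)`.
#'
#' @param sigma_g2 additive genetic variance (required when `fixed = TRUE`).
#' @param sigma_e2 residual variance (required when `fixed = TRUE`).
#' @param fixed if `TRUE` the variances are treated as known.
#' @param nu_g,nu_e prior degrees of freedom (default 4).
#' @param S_g2,S_e2 prior scales; `NULL` = derive from `prior_h2`.
#' @param prior_h2 prior heritability used to derive missing scales.
#' @return a list of class `"varcomp"`.
#' @export
variance_components <- function(sigma_g2 = NULL, sigma_e2 = NULL,
                                fixed = TRUE, nu_g = 4, nu_e = 4,
                                S_g2 = NULL, S_e2 = NULL, prior_h2 = 0.5) {
  if (fixed && (is.null(sigma_g2) || is.null(sigma_e2))) {
    stop("fixed variance components require sigma_g2 and sigma_e2")
  }
  if (!is.null(sigma_g2) && sigma_g2 <= 0) stop("sigma_g2 must be > 0")
  if (!is.null(sigma_e2) && sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, fixed = fixed,
                 nu_g = nu_g, nu_e = nu_e, S_g2 = S_g2, S_e2 = S_e2,
                 prior_h2 = prior_h2),
            class = "varcomp")
}

#' MCMC chain settings
#'
#' @param n_iter total iterations (default 50000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param thin keep every `thin`-th draw (default 10).
#' @param seed integer seed; all samplers draw from R's RNG.
#' @return a list of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_iter = 50000L, burn_in = 10000L, thin = 10L,
                          seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

## scales derived from prior h2 when not given; prior mean of nu*S2/chisq(nu)
## is nu*S2/(nu-2)
fill_vc_scales <- function(vc, var_y) {
  if (is.null(vc$S_g2)) vc$S_g2 <- vc$prior_h2 * var_y * (vc$nu_g - 2) / vc$nu_g
  if (is.null(vc$S_e2)) vc$S_e2 <- (1 - vc$prior_h2) * var_y * (vc$nu_e - 2) / vc$nu_e
  if (is.null(vc$sigma_g2)) vc$sigma_g2 <- vc$prior_h2 * var_y
  if (is.null(vc$sigma_e2)) vc$sigma_e2 <- (1 - vc$prior_h2) * var_y
  vc
}

#' Solve the animal-model mixed-model equations
#'
#' Fits `y = X b + Z u + e` with `u ~ N(0, K sigma_g2)` and i.i.d. residuals
#' for known variances, predicting breeding values for every animal in `K`.
#' `method = "mme"` solves Henderson's equations (requires `K` invertible up
#' to the 1e-8 jitter policy); `method = "gls"` uses the equivalent
#' variance-form solve `u_hat = K Z' V^-1 (y - X b_hat)`, which also handles
#' singular `K` (e.g. an H matrix assembled from the unscaled, centered G).
#'
#' @param phenos data frame with columns `id` and `value`; one record per
#'   animal, the training set.
#' @param K relationship matrix over all animals (ID dimnames).
#' @param vc fixed [variance_components()].
#' @param X optional fixed-effect design (rows = records); default intercept.
#' @param method `"mme"` or `"gls"`.
#' @return list with `b` (fixed-effect solutions; `b[1]` is the mean) and
#'   `ebv` (named vector over all animals in `K`).
#' @export
solve_mme <- function(phenos, K, vc, X = NULL, method = c("mme", "gls")) {
  method <- match.arg(method)
  stopifnot(inherits(vc, "varcomp"))
  if (!vc$fixed) stop("solve_mme requires fixed variance components")
  ids <- rownames(K)
  pos <- match(as.character(phenos$id), ids)
  if (anyNA(pos)) stop("phenotyped animal(s) missing from K")
  y <- phenos$value
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  n_t <- length(y)
  n <- nrow(K)
  if (is.null(X)) X <- matrix(1, n_t, 1L)
  lambda <- vc$sigma_e2 / vc$sigma_g2
  if (method == "mme") {
    Kinv <- tryCatch(chol_solve(K, diag(n), "K"),
                     error = function(e) stop("random-effect block: ", conditionMessage(e)))
    Zt <- matrix(0, n_t, n)
    Zt[cbind(seq_len(n_t), pos)] <- 1
    C <- rbind(
      cbind(crossprod(X), crossprod(X, Zt)),
      cbind(crossprod(Zt, X), crossprod(Zt) + Kinv * lambda)
    )
    rhs <- c(crossprod(X, y), crossprod(Zt, y))
    sol <- tryCatch(solve(C, rhs),
                    error = function(e) stop("coefficient matrix singular (fixed-effect block?): ",
                                             conditionMessage(e)))
    b <- sol[seq_len(ncol(X))]
    u <- sol[-seq_len(ncol(X))]
  } else {
    Kt <- K[, pos, drop = FALSE]
    V <- K[pos, pos, drop = FALSE] * vc$sigma_g2 + diag(vc$sigma_e2, n_t)
    Vi_y <- chol_solve(V, cbind(y, X), "V")
    XtViX <- crossprod(X, Vi_y[, -1L, drop = FALSE])
    b <- solve(XtViX, crossprod(X, Vi_y[, 1L]))
    r <- chol_solve(V, y - X %*% b, "V")
    u <- vc$sigma_g2 * drop(Kt %*% r)
    b <- drop(b)
  }
  list(b = b, ebv = setNames(drop(u), ids))
}

## Gibbs sampler for (mu, u, sigma_g2, sigma_e2) in the eigenspace of Z L,
## K = L L'. After one SVD each sweep is O(n): the rotated coordinates have
## independent full conditionals, and the null-space mass of u enters
## sigma_g2's full conditional through a single chi-square draw.
gibbs_gblup <- function(y, K, pos, vc, chain) {
  n <- nrow(K)
  n_t <- length(y)
  vc <- fill_vc_scales(vc, var(y))
  ch <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-8, n)))
  L <- t(ch)
  W <- L[pos, , drop = FALSE]
  sv <- svd(W)
  d <- sv$d
  r <- length(d)
  n_perp <- n - r
  set.seed(chain$seed)
  sg2 <- vc$sigma_g2
  se2 <- vc$sigma_e2
  mu <- mean(y)
  s <- numeric(r)
  Uty <- crossprod(sv$u, y)
  Ut1 <- colSums(sv$u)
  keep <- seq(chain$burn_in + 1L, chain$n_iter)
  keep <- keep[(keep - chain$burn_in - 1L) %% chain$thin == 0L]
  n_keep <- length(keep)
  s_sum <- numeric(r)
  mu_sum <- 0
  sg2_chain <- se2_chain <- numeric(n_keep)
  k <- 0L
  for (it in seq_len(chain$n_iter)) {
    z <- Uty - Ut1 * mu
    prec <- d^2 / se2 + 1 / sg2
    s <- rnorm(r, (d * z / se2) / prec, sqrt(1 / prec))
    fit <- drop(sv$u %*% (d * s))
    mu <- rnorm(1L, mean(y - fit), sqrt(se2 / n_t))
    q_perp <- if (n_perp > 0L) sg2 * rchisq(1L, n_perp) else 0
    sg2 <- (vc$nu_g * vc$S_g2 + sum(s^2) + q_perp) / rchisq(1L, vc$nu_g + n)
    resid <- y - mu - fit
    se2 <- (vc$nu_e * vc$S_e2 + sum(resid^2)) / rchisq(1L, vc$nu_e + n_t)
    if (it > chain$burn_in && (it - chain$burn_in - 1L) %% chain$thin == 0L) {
      k <- k + 1L
      s_sum <- s_sum + s
      mu_sum <- mu_sum + mu
      sg2_chain[k] <- sg2
      se2_chain[k] <- se2
    }
  }
  ebv <- drop(L %*% (sv$v %*% (s_sum / k)))
  list(mu = mu_sum / k, ebv = setNames(ebv, rownames(K)),
       sigma_g2_chain = sg2_chain, sigma_e2_chain = se2_chain,
       h2_chain = sg2_chain / (sg2_chain + se2_chain))
}

## split-chain potential scale reduction factor
split_psrf <- function(x) {
  m <- length(x) %/% 2L
  if (m < 2L) return(NA_real_)
  halves <- list(x[seq_len(m)], x[m + seq_len(m)])
  W <- mean(vapply(halves, var, 1))
  B <- m * var(vapply(halves, mean, 1))
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Pedigree-based BLUP
#'
#' The animal model `y = 1 mu + Z u + e`, `u ~ N(0, A sigma_g2)`, fitted to
#' phenotypes on all animals (PBLUP) or only on genotyped animals (PBLUP-G,
#' `genotyped_only = TRUE`), predicting breeding values for every pedigree
#' animal either way. With `vc$fixed = FALSE` variances are estimated by
#' Gibbs sampling and posterior-mean EBVs are reported.
#'
#' @param phenos data frame `id, value` (training records).
#' @param A numerator relationship matrix from [build_nrm()].
#' @param vc [variance_components()].
#' @param genotyped_only restrict records to `genotyped_ids`.
#' @param genotyped_ids IDs of genotyped animals (needed when
#'   `genotyped_only = TRUE`).
#' @param chain [mcmc_settings()] used when variances are estimated.
#' @return an object of class `"ssgp_fit"`: `method`, `mu`, `ebv` (all
#'   pedigree animals), `vc`, and when estimated, variance chains, `h2`
#'   (posterior mean heritability) and a split-chain diagnostic.
#' @export
fit_pblup <- function(phenos, A, vc, genotyped_only = FALSE,
                      genotyped_ids = NULL, chain = mcmc_settings()) {
  if (genotyped_only) {
    if (is.null(genotyped_ids)) stop("PBLUP-G needs genotyped_ids")
    phenos <- phenos[as.character(phenos$id) %in% as.character(genotyped_ids), ]
  }
  if (nrow(phenos) == 0L) stop("empty training set")
  label <- if (genotyped_only) "PBLUP-G" else "PBLUP"
  fit_k_model(phenos, A, vc, chain, label)
}

fit_k_model <- function(phenos, K, vc, chain, label, X = NULL,
                        solver = "mme") {
  if (vc$fixed) {
    sol <- solve_mme(phenos, K, vc, X = X, method = solver)
    out <- list(method = label, mu = sol$b[1L], b = sol$b, ebv = sol$ebv,
                vc = vc)
  } else {
    if (!is.null(X)) stop("covariates beyond the mean require fixed variances")
    pos <- match(as.character(phenos$id), rownames(K))
    if (anyNA(pos)) stop("phenotyped animal(s) missing from K")
    g <- gibbs_gblup(phenos$value, K, pos, vc, chain)
    out <- list(method = label, mu = g$mu, ebv = g$ebv,
                vc = variance_components(mean(g$sigma_g2_chain),
                                         mean(g$sigma_e2_chain)),
                sigma_g2_chain = g$sigma_g2_chain,
                sigma_e2_chain = g$sigma_e2_chain,
                h2 = mean(g$h2_chain), h2_chain = g$h2_chain,
                psrf_sigma_g2 = split_psrf(g$sigma_g2_chain))
  }
  class(out) <- "ssgp_fit"
  out
}

#' @export
print.ssgp_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d EBVs, mu = %.4f", x$method, length(x$ebv), x$mu))
  if (!is.null(x$h2)) cat(sprintf(", posterior mean h2 = %.3f", x$h2))
  cat("\n")
  invisible(x)
}

#' Assemble the single-step H matrix
#'
#' Combines the genomic relationship matrix of the genotyped animals with
#' pedigree relationships for the rest:
#' `H_nn = A_ng A_gg^-1 G A_gg^-1 A_gn + (A_nn - A_ng A_gg^-1 A_gn)`,
#' `H_ng = A_ng A_gg^-1 G`, `H_gg = G`. With `G = A_gg` every block collapses
#' and `H = A`. Output rows are ordered non-genotyped then genotyped,
#' following the partition's ID lists.
#'
#' @param partition an [partition_nrm()] object.
#' @param G genomic relationship matrix whose dimnames equal
#'   `partition$genotyped_ids` in the same order.
#' @return symmetric relationship matrix with attribute `kind = "H"`.
#' @export
build_h_matrix <- function(partition, G) {
  stopifnot(inherits(partition, "nrm_partition"))
  if (!identical(rownames(G), partition$genotyped_ids)) {
    stop("ID order of G does not match the partition's genotyped IDs")
  }
  P <- chol_solve(partition$A_gg, partition$A_gn, "A_gg")  # A_gg^-1 A_gn
  GP <- G %*% P
  Hnn <- crossprod(P, GP) + (partition$A_nn - partition$A_ng %*% P)
  Hng <- t(GP)
  H <- rbind(cbind(Hnn, Hng), cbind(GP, G))
  H <- (H + t(H)) / 2
  ids <- c(partition$nongenotyped_ids, partition$genotyped_ids)
  dimnames(H) <- list(ids, ids)
  attr(H, "kind") <- "H"
  H
}

## mu_g covariate (per animal, order non-genotyped then genotyped):
## x = -[A_ng A_gg^-1 1; 1], the genotyped-group column of the single-step
## regression design. Used for exact-equivalence fits.
mu_g_covariate <- function(partition) {
  xn <- -drop(partition$A_ng %*% chol_solve(partition$A_gg,
                                            rep(1, length(partition$genotyped_ids)),
                                            "A_gg"))
  setNames(c(xn, rep(-1, length(partition$genotyped_ids))),
           c(partition$nongenotyped_ids, partition$genotyped_ids))
}

#' Single-step GBLUP
#'
#' Fits the animal model with the combined relationship matrix `H` in place
#' of `A`, using phenotypes on genotyped and non-genotyped animals. Variant
#' `"I"` uses the standard `G` scaled to `A_gg` means; variants `"II"` and
#' `"III"` first fit variant I, derive locus weights from its genotyped-animal
#' EBVs via [reweight_grm()] (one and five iterations respectively), and
#' refit with the reweighted matrix.
#'
#' @param phenos data frame `id, value` over training animals (genotyped and
#'   not).
#' @param partition an [partition_nrm()] object.
#' @param G raw genomic relationship matrix from [build_grm()] (scaled
#'   internally unless `scale = FALSE`).
#' @param vc [variance_components()].
#' @param variant `"I"`, `"II"` or `"III"`.
#' @param genotypes genotype matrix (required for variants II/III).
#' @param chain [mcmc_settings()] for estimated variances.
#' @param scale scale `G` to `A_gg` means first (default `TRUE`).
#' @param include_mu_g add the genotyped-group covariate
#'   `-[A_ng A_gg^-1 1; 1]` to the fixed effects; this is the single-step
#'   regression parameterization and makes the fixed-variance fit exactly
#'   equivalent to SSBR-C with `pi = 0` (fixed variances only).
#' @param solver `"mme"` or `"gls"` (see [solve_mme()]); `"gls"` is needed
#'   when `scale = FALSE` leaves `H` singular.
#' @return an `"ssgp_fit"` (see [fit_pblup()]); EBVs cover all animals.
#' @export
fit_ssgblup <- function(phenos, partition, G, vc, variant = c("I", "II", "III"),
                        genotypes = NULL, chain = mcmc_settings(),
                        scale = TRUE, include_mu_g = FALSE,
                        solver = c("mme", "gls")) {
  variant <- match.arg(variant)
  solver <- match.arg(solver)
  Gs <- if (scale) scale_grm(G, partition$A_gg) else G
  dimnames(Gs) <- list(partition$genotyped_ids, partition$genotyped_ids)
  if (variant != "I") {
    if (is.null(genotypes)) stop("variants II/III need the genotype matrix")
    base <- fit_ssgblup(phenos, partition, G, vc, "I", chain = chain,
                        scale = scale, solver = solver)
    u_g <- base$ebv[partition$genotyped_ids]
    Gs <- reweight_grm(Gs, u_g, genotypes, partition$A_gg,
                       n_iter = if (variant == "II") 1L else 5L)
    dimnames(Gs) <- list(partition$genotyped_ids, partition$genotyped_ids)
  }
  H <- build_h_matrix(partition, Gs)
  X <- NULL
  if (include_mu_g) {
    xg <- mu_g_covariate(partition)
    pos <- match(as.character(phenos$id), names(xg))
    X <- cbind(1, xg[pos])
  }
  fit <- fit_k_model(phenos, H, vc, chain, paste0("SSGBLUP-", variant),
                     X = X, solver = solver)
  fit$variant <- variant
  if (variant != "I") fit$weights <- attr(Gs, "weights")
  fit
}
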