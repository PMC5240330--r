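## Cross-validation design, phenotype pre-adjustment, and the accuracy/bias
## metrics used to compare prediction methods.

#' Pedigree-relationship K-means cross-validation folds
#'
#' Clusters genotyped animals on the rows of `A_gg` (each animal's vector of
#' pedigree relationships to all genotyped animals, Euclidean distance) so
#' that relatives tend to share a fold and relatedness between training and
#' validation sets is reduced. Best of `n_restarts` K-means starts by
#' within-cluster sum of squares; deterministic given `seed`.
#'
#' @param A_gg pedigree relationship block of the genotyped animals.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param n_restarts K-means restarts (default 20).
#' @return an object of class `"fold_assignment"`: `fold_of` (named integer
#'   vector), `k`, `fold_sizes`.
#' @export
make_cv_folds <- function(A_gg, k = 5L, seed = 1L, n_restarts = 20L) {
  n <- nrow(A_gg)
  ids <- rownames(A_gg) %||% as.character(seq_len(n))
  if (k < 2L) stop("cross-validation needs k >= 2")
  if (k > n) stop("more folds than genotyped animals")
  set.seed(seed)
  if (k == n) {
    fold <- sample(seq_len(n))  # singleton folds
  } else {
    km <- kmeans(A_gg, centers = k, nstart = n_restarts, iter.max = 100L)
    fold <- km$cluster
  }
  out <- list(fold_of = setNames(as.integer(fold), ids), k = as.integer(k),
              fold_sizes = as.integer(tabulate(fold, k)))
  if (any(out$fold_sizes == 0L)) stop("empty fold after clustering")
  class(out) <- "fold_assignment"
  out
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("%d folds of sizes %s\n", x$k, paste(x$fold_sizes, collapse = ", ")))
  invisible(x)
}

#' Pre-adjust phenotypes for contemporary group and age
#'
#' Ordinary least-squares adjustment: group effects are training-set group
#' means (age-adjusted when an `age` column is present), expressed as
#' deviations from their mean, and a linear age effect. Validation records
#' are adjusted with training-estimated effects; a group absent from the
#' training set is adjusted with the grand mean (warning). Without a `cg`
#' column the table is returned unchanged.
#'
#' @param raw data frame with `id`, `raw` (unadjusted value) and optional
#'   `cg` (contemporary group) and `age` columns.
#' @param train_ids IDs used to estimate the effects (default: all).
#' @return the table with an adjusted `value` column; estimated effects in
#'   attributes `"cg_effects"` and `"age_beta"`.
#' @export
pre_adjust_phenotypes <- function(raw, train_ids = NULL) {
  if (!("cg" %in% names(raw))) return(raw)
  if (!("raw" %in% names(raw))) stop("need a 'raw' column to adjust")
  tr <- if (is.null(train_ids)) raw else
    raw[as.character(raw$id) %in% as.character(train_ids), ]
  if (nrow(tr) == 0L) stop("empty training set for pre-adjustment")
  has_age <- "age" %in% names(raw)
  tr$cg <- factor(tr$cg)
  fml <- if (has_age) raw ~ 0 + cg + age else raw ~ 0 + cg
  fit <- lm(fml, data = tr)
  cf <- coef(fit)
  age_beta <- if (has_age) unname(cf["age"]) else 0
  g_means <- cf[grep("^cg", names(cf))]
  names(g_means) <- sub("^cg", "", names(g_means))
  effects <- g_means - mean(g_means)
  eff <- effects[as.character(raw$cg)]
  if (anyNA(eff)) {
    warning(sprintf("%d record(s) in contemporary groups unseen in training; grand-mean adjusted",
                    sum(is.na(eff))))
    eff[is.na(eff)] <- 0
  }
  age_term <- if (has_age) age_beta * (raw$age - mean(tr$age)) else 0
  raw$value <- raw$raw - unname(eff) - age_term
  attr(raw, "cg_means") <- g_means
  attr(raw, "cg_effects") <- effects
  attr(raw, "age_beta") <- age_beta
  raw
}

#' Prediction accuracy
#'
#' Pearson correlation between adjusted phenotypes and EBVs of the validation
#' animals, divided by the square root of the trait heritability. Small
#' samples may exceed 1; the value is not clipped.
#'
#' @param y_adj adjusted phenotypes of the validation animals.
#' @param ebv their estimated breeding values.
#' @param h2 trait heritability in (0, 1].
#' @return the accuracy, or `NA` with a warning when either vector has zero
#'   variance.
#' @export
compute_accuracy <- function(y_adj, ebv, h2) {
  stopifnot_scalar_prob(h2, "h2", open_left = TRUE, open_right = FALSE)
  if (length(y_adj) < 3L || length(y_adj) != length(ebv)) {
    stop("need >= 3 paired validation records")
  }
  if (sd(y_adj) == 0 || sd(ebv) == 0) {
    warning("zero variance in phenotypes or EBVs; accuracy undefined")
    return(NA_real_)
  }
  cor(y_adj, ebv) / sqrt(h2)
}

#' Pool per-fold accuracies
#'
#' Size-weighted mean: `sum(n_f * acc_f) / sum(n_f)`. Folds with missing
#' accuracy are dropped with a warning.
#'
#' @param n per-fold validation sizes.
#' @param accuracy per-fold accuracies.
#' @return the pooled accuracy.
#' @export
pool_accuracies <- function(n, accuracy) {
  if (length(n) != length(accuracy)) stop("n and accuracy lengths differ")
  ok <- !is.na(accuracy)
  if (!all(ok)) warning("pooling over available folds only")
  sum(n[ok] * accuracy[ok]) / sum(n[ok])
}

#' Bias regression coefficient
#'
#' OLS slope of adjusted phenotype on EBV; 1 means unbiased, below 1 means
#' predictions are inflated (biased upwards).
#'
#' @inheritParams compute_accuracy
#' @return the slope, or `NA` with a warning on zero EBV variance.
#' @export
compute_bias <- function(y_adj, ebv) {
  if (length(y_adj) < 3L || length(y_adj) != length(ebv)) {
    stop("need >= 3 paired validation records")
  }
  if (sd(ebv) == 0) {
    warning("zero EBV variance; bias slope undefined")
    return(NA_real_)
  }
  unname(coef(lm(y_adj ~ ebv))[2L])
}

method_registry <- function() {
  list(
    pblup    = list(type = "pblup", genotyped_only = FALSE),
    pblup_g  = list(type = "pblup", genotyped_only = TRUE),
    ssgblup1 = list(type = "ssgblup", variant = "I"),
    ssgblup2 = list(type = "ssgblup", variant = "II"),
    ssgblup3 = list(type = "ssgblup", variant = "III"),
    bayesb   = list(type = "bayes", family = "B", estimate_pi = FALSE),
    bayesc   = list(type = "bayes", family = "C", estimate_pi = FALSE),
    bayescpi = list(type = "bayes", family = "C", estimate_pi = TRUE),
    ssbr_b   = list(type = "ssbr", family = "B", estimate_pi = FALSE),
    ssbr_c   = list(type = "ssbr", family = "C", estimate_pi = FALSE),
    ssbr_cpi = list(type = "ssbr", family = "C", estimate_pi = TRUE)
  )
}

#' Cross-validated comparison of prediction methods
#'
#' For each fold, validation animals' phenotypes are dropped from training,
#' the requested model is fitted, validation EBVs are extracted and accuracy
#' and bias are computed against the held-out adjusted phenotypes.
#' Pedigree-based and single-step methods keep non-genotyped phenotypes in
#' every training set; genotyped-only methods (`pblup_g`, `bayesb`, `bayesc`,
#' `bayescpi`) train on genotyped animals only. Validation metrics always use
#' genotyped validation animals.
#'
#' @param data list with `pedigree`, `genotypes` (genotyped animals, complete
#'   codes), and `phenotypes` (`id, value`, adjusted scale).
#' @param method one of `pblup`, `pblup_g`, `ssgblup1`, `ssgblup2`,
#'   `ssgblup3`, `bayesb`, `bayesc`, `bayescpi`, `ssbr_b`, `ssbr_c`,
#'   `ssbr_cpi`.
#' @param folds an [make_cv_folds()] assignment over the genotyped animals.
#' @param h2 heritability used to convert correlations to accuracies.
#' @param vc [variance_components()].
#' @param prior [prior_spec()] for the Bayesian methods (family and
#'   `estimate_pi` are overridden by the method name).
#' @param chain [mcmc_settings()]; the seed is offset by the fold index.
#' @return an object of class `"evaluation_report"`: per-fold data frame
#'   (`method, fold, n, cor, accuracy, bias`) plus `pooled_accuracy`.
#' @export
run_cv <- function(data, method, folds, h2, vc, prior = prior_spec(),
                   chain = mcmc_settings()) {
  stopifnot(inherits(folds, "fold_assignment"))
  reg <- method_registry()
  if (!method %in% names(reg)) {
    stop(sprintf("unknown method '%s'", method))
  }
  spec <- reg[[method]]
  ped <- as_pedigree(data$pedigree)
  phen <- data$phenotypes
  gids <- rownames(data$genotypes)
  A <- build_nrm(ped)
  part <- partition_nrm(A, gids)
  needs_geno <- spec$type %in% c("ssgblup", "ssbr", "bayes")
  G <- if (spec$type %in% c("ssgblup")) build_grm(data$genotypes) else NULL
  design <- if (spec$type == "ssbr") build_ssbr_design(part, data$genotypes) else NULL
  rows <- list()
  train_audit <- list()
  for (f in seq_len(folds$k)) {
    val_ids <- names(folds$fold_of)[folds$fold_of == f]
    train <- phen[!(as.character(phen$id) %in% val_ids), ]
    if (spec$type %in% c("bayes")) {
      train <- train[as.character(train$id) %in% gids, ]
    }
    fchain <- chain
    fchain$seed <- chain$seed + f
    fit <- switch(spec$type,
      pblup = fit_pblup(train, A, vc, genotyped_only = spec$genotyped_only,
                        genotyped_ids = gids, chain = fchain),
      ssgblup = fit_ssgblup(train, part, G, vc, variant = spec$variant,
                            genotypes = data$genotypes, chain = fchain),
      bayes = {
        pr <- prior
        pr$family <- spec$family
        pr$estimate_pi <- spec$estimate_pi
        fit_bayes_regression(train, data$genotypes, pr, vc, chain = fchain)
      },
      ssbr = {
        pr <- prior
        pr$family <- spec$family
        pr$estimate_pi <- spec$estimate_pi
        fit_ssbr(train, design, pr, vc, chain = fchain)
      })
    ebv_val <- fit$ebv[val_ids]
    y_val <- phen$value[match(val_ids, as.character(phen$id))]
    ok <- !is.na(y_val)
    rows[[f]] <- data.frame(
      method = method, fold = f, n = sum(ok),
      cor = cor(y_val[ok], ebv_val[ok]),
      accuracy = compute_accuracy(y_val[ok], ebv_val[ok], h2),
      bias = compute_bias(y_val[ok], ebv_val[ok]))
    train_audit[[f]] <- as.character(train$id)
  }
  per_fold <- do.call(rbind, rows)
  out <- list(method = method, h2 = h2, per_fold = per_fold,
              pooled_accuracy = pool_accuracies(per_fold$n, per_fold$accuracy))
  attr(out, "train_ids") <- train_audit
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s: pooled accuracy %.3f over %d folds (h2 = %.2f)\n",
              x$method, x$pooled_accuracy, nrow(x$per_fold), x$h2))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
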