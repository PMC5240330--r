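## Genotype quality control, allele frequencies, genomic relationship
## matrices (standard and iteratively reweighted), scaling of G to the
## pedigree block, pedigree-vs-genomic conflict screening, and imputation of
## SNP covariates for non-genotyped animals.

hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  q <- (n1 + 2 * n2) / (2 * n)
  if (q <= 0 || q >= 1) return(1)
  exp_counts <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((c(n0, n1, n2) - exp_counts)^2 / exp_counts)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Marker quality control
#'
#' Removes markers by, in order of attribution, missing rate >
#' `missing_max`, minor allele frequency < `maf_min`, and departure from
#' Hardy-Weinberg proportions at `p < hwe_p_min` (one-degree-of-freedom
#' Pearson chi-square of the three genotype classes against expectations from
#' the sample allele frequency). A marker failing several rules is counted
#' once under the first failing rule. MAF, missing rate and the HWE test use
#' non-missing entries only; a fully missing marker is removed under the
#' missing rule.
#'
#' @param genotypes animals x markers matrix of codes 0/1/2, `NA` = missing.
#' @param hwe_p_min Hardy-Weinberg p-value threshold (default `1e-6`).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param missing_max maximum missing rate (default 0.1).
#' @return list with the filtered `genotypes` and a `report` of class
#'   `"qc_report"`: the removal counts and a per-marker table with `maf`,
#'   `missing_rate`, `hwe_pvalue` and the retained flag.
#' @export
qc_filter <- function(genotypes, hwe_p_min = 1e-6, maf_min = 0.01,
                      missing_max = 0.1) {
  if (nrow(genotypes) < 1L || ncol(genotypes) < 1L) {
    stop("qc_filter needs at least one animal and one marker")
  }
  p <- ncol(genotypes)
  miss <- colMeans(is.na(genotypes))
  q <- colMeans(genotypes, na.rm = TRUE) / 2
  q[is.nan(q)] <- NA_real_
  maf <- pmin(q, 1 - q)
  hwe <- vapply(seq_len(p), function(j) {
    g <- genotypes[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    hwe_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  fail_miss <- miss > missing_max | miss == 1
  fail_maf <- !fail_miss & !is.na(maf) & maf < maf_min
  fail_hwe <- !fail_miss & !fail_maf & !is.na(hwe) & hwe < hwe_p_min
  retained <- !(fail_miss | fail_maf | fail_hwe)
  report <- list(
    n_input_markers = p,
    n_removed_missing = sum(fail_miss),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_retained = sum(retained),
    per_marker = data.frame(
      marker = colnames(genotypes) %||% as.character(seq_len(p)),
      maf = maf, missing_rate = miss, hwe_pvalue = hwe, retained = retained
    )
  )
  class(report) <- "qc_report"
  list(genotypes = genotypes[, retained, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d markers in; removed %d (missing), %d (MAF), %d (HWE); %d retained\n",
    x$n_input_markers, x$n_removed_missing, x$n_removed_maf, x$n_removed_hwe,
    x$n_retained))
  invisible(x)
}

#' Mean-impute sporadically missing genotypes
#'
#' Each missing entry is replaced by twice the marker's sample allele
#' frequency (the column mean of non-missing codes); non-missing entries are
#' untouched, so column means are unchanged. This replaces phasing-based
#' imputation and is a documented simplification: downstream methods only
#' need complete real-valued covariate columns.
#'
#' @inheritParams qc_filter
#' @return the genotype matrix with no missing values (numeric).
#' @export
impute_sporadic_missing <- function(genotypes) {
  if (!anyNA(genotypes)) return(genotypes)
  means <- colMeans(genotypes, na.rm = TRUE)
  idx <- which(is.na(genotypes), arr.ind = TRUE)
  genotypes[idx] <- means[idx[, 2L]]
  genotypes
}

#' Allele frequencies
#'
#' `q_i = column sum / (2 * non-missing count)`, the frequency of the allele
#' counted by the 0/1/2 coding.
#'
#' @inheritParams qc_filter
#' @return named numeric vector of per-marker frequencies.
#' @export
allele_freqs <- function(genotypes) {
  nonmiss <- colSums(!is.na(genotypes))
  if (any(nonmiss == 0L)) stop("marker(s) with all genotypes missing")
  colSums(genotypes, na.rm = TRUE) / (2 * nonmiss)
}

#' Standard genomic relationship matrix
#'
#' `G = T T' / sum(2 q_i (1 - q_i))` with `T` the column-centered genotype
#' matrix (`T = M - (1/n) 1 1' M`); allele frequencies are computed from the
#' genotyped animals supplied. The centering makes row sums zero, so the raw
#' `G` is singular until rescaled by [scale_grm()].
#'
#' @param genotypes complete (imputed) genotype matrix of genotyped animals.
#' @return symmetric matrix with ID dimnames, attribute `kind = "GRM"`.
#' @export
build_grm <- function(genotypes) {
  if (nrow(genotypes) < 2L) stop("G needs at least 2 animals")
  if (anyNA(genotypes)) stop("impute missing genotypes before building G")
  q <- colMeans(genotypes) / 2
  denom <- sum(2 * q * (1 - q))
  if (denom <= 0) stop("all markers monomorphic: zero denominator for G")
  Tm <- sweep(genotypes, 2L, colMeans(genotypes))
  G <- tcrossprod(Tm) / denom
  attr(G, "kind") <- "GRM"
  G
}

#' Scale G so its means match the pedigree block
#'
#' Adjusts `G` so that the means of its diagonal and off-diagonal elements
#' equal the corresponding means of `A_gg`, via the affine tuning
#' `G* = beta G + alpha 1 1'` whose two coefficients solve the two
#' mean-matching equations (the adjustment used by the standard single-step
#' software). Because the centered `G` annihilates the ones vector, the
#' `alpha` shift restores a positive eigenvalue in that direction: the
#' scaling removes the singularity introduced by centering whenever the
#' marker count supports full rank otherwise. A literal *multiplicative*
#' rescaling of the off-diagonals would use a negative factor (a centered G
#' has slightly negative mean off-diagonal) and is not what mean-tuning
#' means in practice.
#'
#' @param G genomic relationship matrix from [build_grm()].
#' @param A_gg pedigree relationship block for the same animals, same order.
#' @return the tuned matrix `G*`; coefficients in attribute `"tuning"`.
#' @export
scale_grm <- function(G, A_gg) {
  if (!all(dim(G) == dim(A_gg))) stop("G and A_gg must have the same order")
  md_g <- mean(diag(G))
  if (md_g == 0) stop("mean diagonal of G is zero; cannot scale")
  mo_g <- offdiag_mean(G)
  mo_a <- offdiag_mean(A_gg)
  if (is.na(mo_g)) {
    warning("single animal: off-diagonal scaling skipped")
    out <- G * (mean(diag(A_gg)) / md_g)
    attr(out, "kind") <- "GRM"
    return(out)
  }
  if (md_g == mo_g) stop("degenerate G (diagonal mean equals off-diagonal mean); cannot scale")
  beta <- (mean(diag(A_gg)) - mo_a) / (md_g - mo_g)
  alpha <- mean(diag(A_gg)) - beta * md_g
  out <- beta * G + alpha
  attr(out, "kind") <- "GRM"
  attr(out, "tuning") <- c(alpha = alpha, beta = beta)
  out
}

#' Screen for pedigree-vs-genomic relationship conflicts
#'
#' Flags animal pairs whose genomic relationship `g_ij` contradicts the
#' pedigree expectation `a_ij`. A pair is a `DUPLICATE` when
#' `g_ij >= dup_g_min` and `a_ij <= dup_a_max` (same sample entered twice
#' under IDs recorded as unrelated); it is a `PARENTAGE` conflict when
#' `|g_ij - a_ij| >= rel_delta` and either coefficient is within
#' `rel_delta / 2` of 0.25 (half-sib pairs recorded as unrelated, or
#' recorded half-sibs that are genomically unrelated). Also reports the
#' correlation between off-diagonal NRM and GRM coefficients before and after
#' removing all flagged animals.
#'
#' @param G genomic relationship matrix.
#' @param A_gg matching pedigree block (same animals, same order).
#' @param dup_g_min,dup_a_max,rel_delta thresholds; defaults 0.9, 0.1, 0.2.
#' @return list with `pairs` (data frame `id1, id2, a, g, class`),
#'   `flagged_ids`, `cor_before`, `cor_after`.
#' @export
detect_conflicts <- function(G, A_gg, dup_g_min = 0.9, dup_a_max = 0.1,
                             rel_delta = 0.2) {
  if (!all(dim(G) == dim(A_gg))) stop("G and A_gg must have the same order")
  ids <- rownames(G) %||% as.character(seq_len(nrow(G)))
  ut <- which(upper.tri(G), arr.ind = TRUE)
  g <- G[ut]
  a <- A_gg[ut]
  dup <- g >= dup_g_min & a <= dup_a_max
  par <- !dup & abs(g - a) >= rel_delta &
    (abs(a - 0.25) <= rel_delta / 2 | abs(g - 0.25) <= rel_delta / 2)
  sel <- dup | par
  pairs <- data.frame(id1 = ids[ut[sel, 1L]], id2 = ids[ut[sel, 2L]],
                      a = a[sel], g = g[sel],
                      class = ifelse(dup[sel], "DUPLICATE", "PARENTAGE"),
                      stringsAsFactors = FALSE)
  flagged <- unique(c(pairs$id1, pairs$id2))
  cor_before <- if (length(g) > 2L) cor(a, g) else NA_real_
  keep <- !(ids[ut[, 1L]] %in% flagged) & !(ids[ut[, 2L]] %in% flagged)
  cor_after <- if (sum(keep) > 2L) cor(a[keep], g[keep]) else NA_real_
  list(pairs = pairs, flagged_ids = flagged,
       cor_before = cor_before, cor_after = cor_after)
}

#' Impute SNP covariates for non-genotyped animals
#'
#' Pedigree-expected covariates `M_hat_n = A_ng A_gg^-1 M_g`, solved as a
#' linear system (never via an explicit inverse). Rows for non-genotyped
#' animals unrelated to every genotyped animal are exactly zero.
#'
#' @param partition an [partition_nrm()] object.
#' @param M_g genotype matrix of the genotyped animals, rows in any order (a
#'   superset of `partition$genotyped_ids` is allowed).
#' @return real-valued matrix of imputed covariates, one row per
#'   non-genotyped animal.
#' @export
impute_nongenotyped <- function(partition, M_g) {
  stopifnot(inherits(partition, "nrm_partition"))
  M_g <- M_g[partition$genotyped_ids, , drop = FALSE]
  out <- partition$A_ng %*% chol_solve(partition$A_gg, M_g, "A_gg")
  dimnames(out) <- list(partition$nongenotyped_ids, colnames(M_g))
  out
}

#' Iteratively reweighted genomic relationship matrix
#'
#' Starting from a scaled standard `G`, each iteration back-solves marker
#' effects from the current matrix and the supplied genotyped-animal EBVs
#' (`alpha = D T' G^-1 u_g`), derives locus weights
#' `d_i` proportional to `alpha_i^2 2 q_i (1 - q_i)` normalized so they sum
#' to the marker count, rebuilds `G = T D T' / sum(2 q (1 - q))` and rescales
#' its means to `A_gg`. One iteration gives the matrix used by the reweighted
#' single-step variant, five iterations the heavily reweighted one.
#'
#' @param G0 scaled standard genomic relationship matrix.
#' @param ebv_genotyped named vector of genotyped-animal EBVs from the
#'   standard single-step fit.
#' @param genotypes genotype matrix of the same animals.
#' @param A_gg pedigree block used for rescaling.
#' @param n_iter number of reweighting iterations (>= 1).
#' @return the reweighted, rescaled matrix; locus weights in attribute
#'   `"weights"`.
#' @export
reweight_grm <- function(G0, ebv_genotyped, genotypes, A_gg, n_iter = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  ids <- rownames(G0)
  u <- ebv_genotyped[ids]
  if (anyNA(u)) stop("EBVs missing for some genotyped animals")
  q <- colMeans(genotypes[ids, , drop = FALSE]) / 2
  Tm <- sweep(genotypes[ids, , drop = FALSE], 2L, colMeans(genotypes[ids, , drop = FALSE]))
  denom <- sum(2 * q * (1 - q))
  p <- ncol(Tm)
  d <- rep(1, p)
  G <- G0
  for (it in seq_len(n_iter)) {
    alpha <- d * drop(crossprod(Tm, chol_solve(G, u, "G")))
    w <- alpha^2 * 2 * q * (1 - q)
    if (sum(w) == 0) {
      warning("all marker effects zero; weights reset to uniform")
      w <- rep(1, p)
    }
    d <- w * p / sum(w)
    G <- tcrossprod(sweep(Tm, 2L, d, `*`), Tm) / denom
    G <- scale_grm(G, A_gg)
  }
  attr(G, "kind") <- "GRM"
  attr(G, "weights") <- d
  G
}
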