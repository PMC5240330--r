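## Window-variance GWAS: proportion of genetic variance attributable to
## non-overlapping genomic windows, computed from posterior draws of marker
## effects.

#' Window-variance GWAS from posterior marker-effect draws
#'
#' Tiles each chromosome into non-overlapping windows of `window_bp`
#' (half-open intervals anchored at position 0, window index
#' `floor(pos_bp / window_bp)`). For every retained posterior draw, the
#' window genetic values are the centered window genotypes times the window's
#' effects; the window's proportion of genetic variance in that draw is the
#' variance of its genetic values across animals divided by the sum of the
#' window variances, so per-draw proportions sum to one exactly. The table
#' reports posterior means. Draws with all effects zero carry no genetic
#' variance and are skipped with a warning.
#'
#' @param posterior an `"ssgp_posterior"` fitted with `keep_draws = TRUE`.
#' @param genotypes genotype matrix of the genotyped animals (the training
#'   covariates).
#' @param map marker map (`marker, chrom, pos_bp`) covering every genotype
#'   column, same order.
#' @param window_bp window size in base pairs (default 1 Mb).
#' @return data frame of class `"window_variance_table"`: `chrom, start_bp,
#'   end_bp, n_markers, mean_prop_var, rank` (rank 1 = largest), with the
#'   number of draws used in attribute `"n_draws"`.
#' @export
window_variance <- function(posterior, genotypes, map, window_bp = 1e6) {
  draws <- posterior$alpha_draws
  if (is.null(draws) || nrow(draws) == 0L) {
    stop("posterior has no retained marker-effect draws; refit with keep_draws = TRUE")
  }
  if (!identical(as.character(map$marker), colnames(genotypes))) {
    stop("marker map does not match the genotype columns (order and names)")
  }
  if (ncol(draws) != ncol(genotypes)) stop("draws and genotypes disagree on marker count")
  Tm <- sweep(genotypes, 2L, colMeans(genotypes))
  win_start <- floor(map$pos_bp / window_bp)
  key <- paste(map$chrom, win_start, sep = ":")
  uk <- unique(key[order(map$chrom, win_start)])
  idx_of <- split(seq_len(ncol(Tm)), factor(key, levels = uk))
  n_win <- length(uk)
  n_draws <- nrow(draws)
  V <- matrix(0, n_win, n_draws)  # per-window, per-draw genetic variance
  for (w in seq_len(n_win)) {
    idx <- idx_of[[w]]
    Gw <- Tm[, idx, drop = FALSE] %*% t(draws[, idx, drop = FALSE])
    V[w, ] <- apply(Gw, 2L, var)
  }
  tot <- colSums(V)
  use <- tot > 0
  if (!any(use)) stop("every retained draw has zero genetic variance")
  if (!all(use)) {
    warning(sprintf("%d draw(s) with all effects zero skipped", sum(!use)))
  }
  prop <- sweep(V[, use, drop = FALSE], 2L, tot[use], `/`)
  mean_prop <- rowMeans(prop)
  parts <- strsplit(uk, ":", fixed = TRUE)
  out <- data.frame(
    chrom = as.integer(vapply(parts, `[`, "", 1L)),
    start_bp = as.numeric(vapply(parts, `[`, "", 2L)) * window_bp,
    n_markers = lengths(idx_of),
    mean_prop_var = mean_prop)
  out$end_bp <- out$start_bp + window_bp
  out$rank <- rank(-out$mean_prop_var, ties.method = "first")
  out <- out[, c("chrom", "start_bp", "end_bp", "n_markers", "mean_prop_var", "rank")]
  attr(out, "n_draws") <- sum(use)
  class(out) <- c("window_variance_table", class(out))
  rownames(out) <- NULL
  out
}
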