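## File formats, input cross-validation and the end-to-end pipeline runner.
## All artifacts are plain text: CSV tables, a PLINK-.raw-like genotype
## matrix, and a JSON manifest recording seeds, settings and checksums.

#' Read and write genotype matrices as PLINK-.raw-like text
#'
#' Space-separated text with a header of marker IDs, one row per animal
#' (`id` then 0/1/2 codes, `NA` for missing).
#'
#' @param genotypes animals x markers matrix with ID dimnames.
#' @param path file path.
#' @return `read_genotypes()` returns the matrix with ID dimnames.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$id)
  storage.mode(m) <- "numeric"
  m
}

#' Read/write the marker map and phenotype tables
#'
#' Marker map: CSV `marker,chrom,pos_bp`. Phenotypes: CSV `id,value[,...]`.
#' Truth: CSV `id,tbv`.
#'
#' @param map,phenotypes,truth the tables.
#' @param path file path.
#' @return the read functions return data frames.
#' @export
write_marker_map <- function(map, path) {
  write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_marker_map
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_phenotypes <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_marker_map
#' @export
write_truth <- function(truth, path) {
  write.csv(data.frame(id = names(truth$tbv), tbv = unname(truth$tbv)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a relationship matrix as inspectable text
#'
#' Space-separated: a header of IDs, then one row per animal (`id` followed
#' by the coefficients).
#'
#' @param M symmetric matrix with ID dimnames.
#' @param path file path.
#' @export
write_matrix <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  m <- read_genotypes(path)
  colnames(m) <- rownames(m)
  m
}

#' Read and cross-validate an input bundle
#'
#' Loads pedigree, genotypes, marker map and phenotypes from the paths in
#' `config` and checks that genotyped and phenotyped animals exist in the
#' pedigree and that every genotype column has a map row.
#'
#' @param config list with elements `pedigree`, `genotypes`, `map`,
#'   `phenotypes` (file paths).
#' @return list with the four parsed objects.
#' @export
read_inputs <- function(config) {
  ped <- read_pedigree(config$pedigree)
  geno <- read_genotypes(config$genotypes)
  map <- read_marker_map(config$map)
  phen <- read_phenotypes(config$phenotypes)
  pid <- as.character(ped$id)
  miss_g <- setdiff(rownames(geno), pid)
  if (length(miss_g)) {
    stop(sprintf("%d genotyped animal(s) absent from the pedigree (e.g. %s)",
                 length(miss_g), miss_g[1L]))
  }
  miss_p <- setdiff(as.character(phen$id), pid)
  if (length(miss_p)) {
    stop(sprintf("%d phenotyped animal(s) absent from the pedigree (e.g. %s)",
                 length(miss_p), miss_p[1L]))
  }
  if (!identical(colnames(geno), as.character(map$marker))) {
    stop("genotype columns and marker map disagree (unmapped or reordered markers)")
  }
  list(pedigree = ped, genotypes = geno, map = map, phenotypes = phen)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a data bundle, then: marker QC and mean imputation,
#' pedigree-vs-genomic conflict screening (flagged animals removed when
#' `remove_conflicts`), relationship matrices, K-means fold assignment,
#' cross-validation of every requested method, and optionally a window GWAS
#' from a BayesB fit on all genotyped animals. Artifacts and a JSON manifest
#' (settings, seeds, file checksums) are written to `out_dir`.
#'
#' @param config list with elements:
#'   * `sim`: a [sim_config()] (or `paths`: a list for [read_inputs()]),
#'   * `out_dir`: output directory,
#'   * `methods`: character vector of [run_cv()] method names,
#'   * `h2`: trait heritability,
#'   * `k_folds`: folds (default 5),
#'   * `vc`: [variance_components()] (default: estimated),
#'   * `prior`: [prior_spec()] (default BayesC pi = 0.95),
#'   * `chain`: [mcmc_settings()],
#'   * `remove_conflicts`: drop flagged animals (default `TRUE`),
#'   * `gwas`: `NULL` or a list with `pi` (BayesB window GWAS settings),
#'   * `seed`: master seed (default 1).
#' @return list with `reports` (one [run_cv()] report per method), `qc`,
#'   `conflicts`, `folds`, `gwas`, and `manifest` (also written to disk).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  h2 <- config$h2 %||% 0.5
  chain <- config$chain %||% mcmc_settings(2000L, 500L, 5L, seed = seed)
  vc <- config$vc %||% variance_components(fixed = FALSE, prior_h2 = h2)
  prior <- config$prior %||% prior_spec("C", pi = 0.95)
  if (!is.null(config$sim)) {
    bundle <- simulate_dataset(config$sim)
    write_pedigree(bundle$pedigree, file.path(config$out_dir, "pedigree.csv"))
    write_genotypes(bundle$genotypes, file.path(config$out_dir, "genotypes.raw"))
    write_marker_map(bundle$map, file.path(config$out_dir, "map.csv"))
    write_phenotypes(bundle$phenotypes, file.path(config$out_dir, "phenotypes.csv"))
    write_truth(bundle$truth, file.path(config$out_dir, "truth.csv"))
  } else if (!is.null(config$paths)) {
    bundle <- read_inputs(config$paths)
  } else {
    stop("config needs either 'sim' or 'paths'")
  }
  ## stage: QC
  qc <- qc_filter(bundle$genotypes)
  geno <- impute_sporadic_missing(qc$genotypes)
  map <- bundle$map[bundle$map$marker %in% colnames(geno), , drop = FALSE]
  write.csv(qc$report$per_marker, file.path(config$out_dir, "qc_report.csv"),
            row.names = FALSE)
  ## stage: conflict screening
  ped <- as_pedigree(bundle$pedigree)
  A <- build_nrm(ped)
  gids <- rownames(geno)
  G0 <- build_grm(geno)
  dimnames(G0) <- list(gids, gids)
  conf <- detect_conflicts(G0, A[gids, gids])
  write.csv(conf$pairs, file.path(config$out_dir, "conflicts.csv"),
            row.names = FALSE)
  if (isTRUE(config$remove_conflicts %||% TRUE) && length(conf$flagged_ids)) {
    geno <- geno[!(rownames(geno) %in% conf$flagged_ids), , drop = FALSE]
    gids <- rownames(geno)
  }
  ## stage: folds
  folds <- make_cv_folds(A[gids, gids], k = config$k_folds %||% 5L,
                         seed = seed + 1L)
  ## stage: cross-validation
  data <- list(pedigree = ped, genotypes = geno,
               phenotypes = bundle$phenotypes)
  methods <- config$methods %||% c("pblup", "ssgblup1")
  reports <- lapply(methods, function(m) {
    run_cv(data, m, folds, h2 = h2, vc = vc, prior = prior, chain = chain)
  })
  names(reports) <- methods
  rep_df <- do.call(rbind, lapply(reports, `[[`, "per_fold"))
  pooled <- data.frame(method = methods, fold = NA, n = NA, cor = NA,
                       accuracy = vapply(reports, `[[`, 1, "pooled_accuracy"),
                       bias = NA)
  write.csv(rbind(rep_df, pooled), file.path(config$out_dir, "cv_report.csv"),
            row.names = FALSE)
  ## stage: GWAS (optional)
  gw <- NULL
  if (!is.null(config$gwas)) {
    pr <- prior_spec("B", pi = config$gwas$pi %||% 0.98)
    post <- fit_bayes_regression(
      bundle$phenotypes[as.character(bundle$phenotypes$id) %in% gids, ],
      geno, pr, vc, chain = chain, keep_draws = TRUE)
    gw <- window_variance(post, geno, map,
                          window_bp = config$gwas$window_bp %||% 1e6)
    write.csv(as.data.frame(gw), file.path(config$out_dir, "gwas_windows.csv"),
              row.names = FALSE)
  }
  ## manifest
  arts <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    seed = seed, h2 = h2, methods = methods,
    chain = unclass(chain),
    checksums = as.list(tools::md5sum(arts))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(reports = reports, qc = qc$report, conflicts = conf, folds = folds,
       gwas = gw, manifest = manifest)
}
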