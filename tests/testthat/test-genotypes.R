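offdiag_mean_test <- function(M) (sum(M) - sum(diag(M))) / (nrow(M) * (nrow(M) - 1))

test_that("qc_filter applies the three rules with first-failure attribution", {
  ## columns: perfect HWE, hard HWE failure, monomorphic, too much missing,
  ## and one failing both missing and MAF (attributed to missing)
  n <- 100
  g <- cbind(
    hwe_ok   = c(rep(0, 25), rep(1, 50), rep(2, 25)),
    hwe_bad  = c(rep(0, 50), rep(2, 50)),
    mono     = rep(0, n),
    missing  = c(rep(NA, 20), rep(1, 80)),
    miss_maf = c(rep(NA, 20), rep(0, 80))
  )
  res <- qc_filter(g)
  rep <- res$report
  expect_equal(rep$n_input_markers, 5)
  expect_equal(rep$n_removed_missing, 2)  # 'missing' and 'miss_maf'
  expect_equal(rep$n_removed_maf, 1)      # 'mono'
  expect_equal(rep$n_removed_hwe, 1)      # 'hwe_bad'
  expect_equal(rep$n_retained, 1)
  expect_identical(colnames(res$genotypes), "hwe_ok")
  expect_equal(rep$n_retained + rep$n_removed_missing + rep$n_removed_maf +
                 rep$n_removed_hwe, rep$n_input_markers)

  pm <- rep$per_marker
  expect_equal(pm$maf[1], 0.5)
  expect_equal(pm$hwe_pvalue[1], 1)
  ## chi-square for total heterozygote deficit at q = 0.5 is n; independent
  ## check against R's chi-square test statistic
  chi_oracle <- unname(suppressWarnings(
    stats::chisq.test(c(50, 0, 50), p = c(0.25, 0.5, 0.25))$statistic))
  expect_equal(chi_oracle, 100)
  expect_equal(pm$hwe_pvalue[2], pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(pm$hwe_pvalue[2], 1e-6)

  ## fully missing marker removed under the missing rule, no division by zero
  allna <- matrix(NA_real_, 10, 1, dimnames = list(NULL, "x"))
  expect_equal(qc_filter(allna)$report$n_removed_missing, 1)
})

test_that("qc_filter is idempotent", {
  d <- small_world(seed = 3)
  g <- d$genotypes
  g[sample(length(g), 50)] <- NA
  once <- qc_filter(g)
  twice <- qc_filter(once$genotypes)
  expect_identical(once$genotypes, twice$genotypes)
  expect_equal(twice$report$n_retained, twice$report$n_input_markers)
})

test_that("mean imputation fills missing entries without moving column means", {
  g <- cbind(a = c(0, 2, NA), b = c(1, 1, 1))
  out <- impute_sporadic_missing(g)
  expect_equal(unname(out[3, "a"]), 1.0)
  expect_identical(impute_sporadic_missing(g[, 2, drop = FALSE]),
                   g[, 2, drop = FALSE])
  expect_equal(colMeans(out), colMeans(g, na.rm = TRUE))
})

test_that("allele frequencies are column means over non-missing entries", {
  expect_equal(unname(allele_freqs(cbind(c(0, 1, 2)))), 0.5)
  expect_equal(unname(allele_freqs(cbind(c(2, 2, 2)))), 1.0)
  expect_error(allele_freqs(cbind(c(NA, NA))), "missing")
  ## gene-dropped descendants track the founder frequency within 3 SE
  cfg <- sim_config(n_founders = 40, n_generations = 1,
                    matings_per_generation = 250, offspring_per_mating = 4,
                    n_snps = 60, seed = 19)
  ped <- simulate_pedigree(cfg)
  gd <- simulate_genotypes(ped, cfg)
  founders <- as.character(ped$id[ped$generation == 0])
  qf <- allele_freqs(gd$genotypes[founders, ])
  qd <- allele_freqs(gd$genotypes[setdiff(rownames(gd$genotypes), founders), ])
  dif <- qd - qf
  expect_lt(abs(mean(dif)), 3 * sd(dif) / sqrt(length(dif)))
})

test_that("build_grm matches the hand-computed oracle and centering algebra", {
  expect_error(build_grm(matrix(c(0, 0, 2, 2), 2, 2)), "monomorphic")
  same <- matrix(rep(c(0, 1, 2, 1), 3), 3, 4, byrow = TRUE)
  ## identical animals: centering annihilates everything
  expect_equal(unname(build_grm(same)), matrix(0, 3, 3), ignore_attr = TRUE)

  g <- matrix(c(0, 1, 2), 3, 1, dimnames = list(1:3, "m"))
  G <- build_grm(g)
  expect_equal(unname(G), rbind(c(2, 0, -2), c(0, 0, 0), c(-2, 0, 2)),
               ignore_attr = TRUE)

  d <- small_world(seed = 29)
  G2 <- build_grm(d$genotypes)
  expect_lt(max(abs(rowSums(G2))), 1e-8)          # G 1 = 0
  expect_equal(offdiag_mean_test(G2), -mean(diag(G2)) / (nrow(G2) - 1),
               tolerance = 1e-10)
})

test_that("scale_grm matches means to A_gg and removes the centering singularity", {
  cfg <- sim_config(n_founders = 40, n_generations = 3,
                    matings_per_generation = 20, offspring_per_mating = 3,
                    n_snps = 400, genotyped_generations = 2:3, seed = 37)
  d <- simulate_dataset(cfg)
  A <- build_nrm(d$pedigree)
  gids <- rownames(d$genotypes)
  A_gg <- A[gids, gids]
  G <- build_grm(d$genotypes)
  Gs <- scale_grm(G, A_gg)
  expect_equal(mean(diag(Gs)), mean(diag(A_gg)), tolerance = 1e-12)
  expect_equal(offdiag_mean_test(Gs), offdiag_mean_test(A_gg), tolerance = 1e-12)
  ## centering makes raw G singular; the tuning restores full rank (p > n)
  ev_raw <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev_scl <- eigen(Gs, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(abs(ev_raw)), 1e-10)
  expect_gt(min(ev_scl), 0)
  ## already-matching means: identity transform
  expect_equal(scale_grm(A_gg, A_gg), A_gg, ignore_attr = TRUE)
  ## parent-offspring pairs: realized ~ expected relationships after scaling
  ped <- as.data.frame(d$pedigree)
  po <- ped[ped$sire != 0 & as.character(ped$id) %in% gids &
              as.character(ped$sire) %in% gids, ]
  idx <- cbind(as.character(po$id), as.character(po$sire))
  expect_equal(mean(Gs[idx]), mean(A_gg[idx]), tolerance = 0.05)
})

test_that("conflict screening flags planted errors and stays quiet on clean data", {
  d <- small_world(seed = 43)
  pl <- plant_conflicts(d$genotypes, d$pedigree, n_duplicates = 1,
                        n_parentage_errors = 1, seed = 4)
  A <- build_nrm(pl$pedigree)
  gids <- rownames(pl$genotypes)
  G <- scale_grm(build_grm(pl$genotypes), A[gids, gids])
  dimnames(G) <- list(gids, gids)
  conf <- detect_conflicts(G, A[gids, gids])
  dup <- pl$errors[pl$errors$type == "duplicate", ]
  hit <- conf$pairs$class == "DUPLICATE" &
    ((conf$pairs$id1 == dup$id & conf$pairs$id2 == dup$counterpart) |
       (conf$pairs$id2 == dup$id & conf$pairs$id1 == dup$counterpart))
  expect_true(any(hit))
  ## removing flagged animals moves the NRM-GRM correlation up
  expect_gt(conf$cor_after, conf$cor_before)

  clean <- small_world(seed = 47)
  Ac <- build_nrm(clean$pedigree)
  gc <- rownames(clean$genotypes)
  Gc <- scale_grm(build_grm(clean$genotypes), Ac[gc, gc])
  dimnames(Gc) <- list(gc, gc)
  confc <- detect_conflicts(Gc, Ac[gc, gc])
  expect_equal(sum(confc$pairs$class == "DUPLICATE"), 0)
})

test_that("imputed covariates obey the conditional-expectation identities", {
  ## trio: genotyped unrelated parents, non-genotyped offspring, plus an
  ## unrelated non-genotyped founder
  ped <- as_pedigree(data.frame(id = 1:4, sire = c(0, 0, 1, 0),
                                dam = c(0, 0, 2, 0)))
  A <- build_nrm(ped)
  M_g <- matrix(c(2, 0), 2, 1, dimnames = list(c("1", "2"), "m"))
  part <- partition_nrm(A, c("1", "2"))
  Mh <- impute_nongenotyped(part, M_g)
  expect_equal(Mh["3", "m"], 1.0)   # parent average
  expect_equal(Mh["4", "m"], 0.0)   # unrelated: annihilated
  ## invariance to the ordering of genotyped animals
  part2 <- partition_nrm(A, c("2", "1"))
  Mh2 <- impute_nongenotyped(part2, M_g)
  expect_equal(Mh2, Mh[rownames(Mh2), , drop = FALSE])
})

test_that("reweight_grm keeps weights normalized and reacts to planted QTL", {
  cfg <- sim_config(n_founders = 30, n_generations = 2,
                    matings_per_generation = 30, offspring_per_mating = 3,
                    n_snps = 300, n_chromosomes = 6, chromosome_length_bp = 5e6,
                    h2 = 0.5, architecture = "major_qtl", n_qtl = 3,
                    qtl_variance_fraction = 0.3,
                    genotyped_generations = 1:2, seed = 53)
  d <- simulate_dataset(cfg)
  A <- build_nrm(d$pedigree)
  gids <- rownames(d$genotypes)
  A_gg <- A[gids, gids]
  G0 <- scale_grm(build_grm(d$genotypes), A_gg)
  dimnames(G0) <- list(gids, gids)

  ## zero EBVs: uniform weights, matrix unchanged (up to rescaling)
  expect_warning(
    Gz <- reweight_grm(G0, setNames(rep(0, length(gids)), gids),
                       d$genotypes, A_gg),
    "uniform")
  expect_equal(unname(Gz), unname(G0), tolerance = 1e-10, ignore_attr = TRUE)

  ## weights sum to p after every iteration
  u <- d$truth$tbv[gids]
  G3 <- reweight_grm(G0, u, d$genotypes, A_gg, n_iter = 3)
  expect_equal(sum(attr(G3, "weights")), ncol(d$genotypes), tolerance = 1e-8)

  G1 <- reweight_grm(G0, u, d$genotypes, A_gg, n_iter = 1)
  w <- attr(G1, "weights")
  expect_gt(mean(w[d$truth$qtl_idx]), mean(w[-d$truth$qtl_idx]))
})
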