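test_that("config validation enforces the stated world", {
  expect_error(sim_config(h2 = 0), "h2")
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(founder_maf_range = c(0, 0.5)), "founder_maf_range")
  expect_error(sim_config(architecture = "major_qtl", n_qtl = 0), "n_qtl")
  expect_error(sim_config(n_founders = 1), "founders")
})

test_that("simulated pedigrees have the promised structure", {
  cfg <- sim_config(n_founders = 10, n_generations = 3,
                    matings_per_generation = 5, offspring_per_mating = 2,
                    seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10 + 3 * 5 * 2)
  expect_equal(sort(unique(ped$generation)), 0:3)
  founders <- ped$generation == 0
  expect_true(all(ped$sire[founders] == 0 & ped$dam[founders] == 0))
  expect_true(all(match(ped$sire[!founders], ped$id) < which(!founders)))
  ## parents come from the previous generation
  gen_of <- setNames(ped$generation, ped$id)
  expect_true(all(gen_of[as.character(ped$sire[!founders])] ==
                    ped$generation[!founders] - 1))

  two <- simulate_pedigree(sim_config(n_founders = 2, n_generations = 1,
                                      matings_per_generation = 1,
                                      offspring_per_mating = 2, seed = 1))
  expect_equal(nrow(two), 4)
  expect_equal(two$sire[3:4], c(1L, 1L))
  expect_equal(two$dam[3:4], c(2L, 2L))

  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))

  ## a generation of a single animal cannot mate
  bad <- sim_config(n_founders = 2, n_generations = 2,
                    matings_per_generation = 1, offspring_per_mating = 1)
  expect_error(simulate_pedigree(bad), "feasible matings")
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  d <- small_world(seed = 13)
  ped <- d$pedigree
  codes <- d$genotypes_full
  si <- match(ped$sire, ped$id)
  non <- which(!is.na(si))
  for (i in sample(non, 20)) {
    s <- codes[si[i], ]
    dd <- codes[match(ped$dam[i], ped$id), ]
    lo <- (s == 2) + (dd == 2)
    hi <- (s >= 1) + (dd >= 1)
    off <- codes[i, ]
    expect_true(all(off >= lo & off <= hi))
  }
  g2 <- simulate_genotypes(ped, d$config)
  expect_identical(g2$genotypes, codes)
  expect_identical(g2$map, d$map)
  ## map positions strictly increase within chromosome
  by_chr <- split(d$map$pos_bp, d$map$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), TRUE)))
})

test_that("descendant allele frequencies track founder frequencies", {
  cfg <- sim_config(n_founders = 60, n_generations = 1,
                    matings_per_generation = 500, offspring_per_mating = 4,
                    n_snps = 150, seed = 31)
  ped <- simulate_pedigree(cfg)
  gd <- simulate_genotypes(ped, cfg)
  founders <- as.character(ped$id[ped$generation == 0])
  desc <- setdiff(rownames(gd$genotypes), founders)
  qf <- colMeans(gd$genotypes[founders, ]) / 2
  qd <- colMeans(gd$genotypes[desc, ]) / 2
  dif <- qd - qf
  expect_lt(abs(mean(dif)), 3 * sd(dif) / sqrt(length(dif)))
})

test_that("polygenic phenotypes hit the target heritability", {
  cfg <- sim_config(n_founders = 100, n_generations = 2,
                    matings_per_generation = 200, offspring_per_mating = 6,
                    n_snps = 150, h2 = 0.5, seed = 17)
  ped <- simulate_pedigree(cfg)   # 2500 animals
  gd <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(gd$genotypes, gd$map, ped, cfg)
  fit <- lm(ph$phenotypes$value ~ ph$truth$tbv)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(summary(fit)$r.squared, 0.5, tolerance = 0.05)
  expect_equal(ph$truth$sigma_g2_true /
                 (ph$truth$sigma_g2_true + ph$truth$sigma_e2_true),
               0.5, tolerance = 0.01)
})

test_that("major-QTL architecture concentrates the stated variance fraction", {
  cfg <- sim_config(n_founders = 100, n_generations = 2,
                    matings_per_generation = 150, offspring_per_mating = 6,
                    n_snps = 300, n_chromosomes = 6, chromosome_length_bp = 5e6,
                    h2 = 0.5, architecture = "major_qtl", n_qtl = 3,
                    qtl_variance_fraction = 0.15, seed = 23)
  ped <- simulate_pedigree(cfg)
  gd <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(gd$genotypes, gd$map, ped, cfg)
  tr <- ph$truth
  expect_length(tr$qtl_idx, 3)
  ## QTL sit in distinct 1-Mb windows
  win <- paste(gd$map$chrom, floor(gd$map$pos_bp / 1e6))[tr$qtl_idx]
  expect_equal(anyDuplicated(win), 0L)
  Tm <- sweep(gd$genotypes, 2, colMeans(gd$genotypes))
  g_q <- drop(Tm[, tr$qtl_idx] %*% tr$qtl_effects)
  expect_equal(var(g_q) / var(tr$tbv), 0.15, tolerance = 0.05)
  ## too many QTL for the available windows
  expect_error(
    simulate_phenotypes(gd$genotypes, gd$map,  ped,
                        sim_config(n_snps = 300, n_chromosomes = 6,
                                   chromosome_length_bp = 5e6,
                                   architecture = "major_qtl", n_qtl = 1000)),
    "windows")
})

test_that("realized heritability is calibrated across replicates", {
  h2s <- vapply(1:20, function(r) {
    cfg <- sim_config(n_founders = 100, n_generations = 1,
                      matings_per_generation = 500, offspring_per_mating = 4,
                      n_snps = 80, h2 = 0.4, seed = 100 + r)
    ped <- simulate_pedigree(cfg)   # 2100 animals
    gd <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(gd$genotypes, gd$map, ped, cfg)
    var(ph$truth$tbv) / var(ph$phenotypes$value)
  }, numeric(1))
  expect_equal(mean(h2s), 0.4, tolerance = 0.03)
})

test_that("masking keeps non-genotyped animals in pedigree and phenotypes", {
  d <- small_world(seed = 41)
  cfg_all <- d$config
  cfg_all$genotyped_generations <- 0:3
  expect_identical(mask_genotypes(d$genotypes_full, d$pedigree, cfg_all),
                   d$genotypes_full)
  cfg_last <- d$config
  cfg_last$genotyped_generations <- 3L
  m <- mask_genotypes(d$genotypes_full, d$pedigree, cfg_last)
  expect_equal(nrow(m), sum(d$pedigree$generation == 3))
  masked_ids <- setdiff(d$pedigree$id, as.integer(rownames(m)))
  expect_true(all(masked_ids %in% d$pedigree$id))
  expect_true(all(masked_ids %in% d$phenotypes$id))
})

test_that("planted conflicts are recorded and well-formed", {
  d <- small_world(seed = 55)
  none <- plant_conflicts(d$genotypes, d$pedigree, 0, 0)
  expect_identical(none$genotypes, d$genotypes)
  expect_equal(nrow(none$errors), 0L)

  pl <- plant_conflicts(d$genotypes, d$pedigree, n_duplicates = 2,
                        n_parentage_errors = 2, seed = 8)
  expect_equal(sum(pl$errors$type == "duplicate"), 2)
  expect_equal(sum(pl$errors$type == "parentage"), 2)
  A <- build_nrm(pl$pedigree)
  for (r in which(pl$errors$type == "duplicate")) {
    dup <- as.character(pl$errors$id[r])
    src <- as.character(pl$errors$counterpart[r])
    expect_identical(pl$genotypes[dup, ], pl$genotypes[src, ])
    expect_equal(A[dup, src], 0)
  }
  for (r in which(pl$errors$type == "parentage")) {
    child <- pl$errors$id[r]
    expect_equal(pl$pedigree$sire[pl$pedigree$id == child],
                 pl$errors$new_parent[r])
  }
  expect_identical(pl$errors,
                   plant_conflicts(d$genotypes, d$pedigree, 2, 2, seed = 8)$errors)
})
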