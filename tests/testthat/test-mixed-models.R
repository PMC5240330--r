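test_that("solve_mme obeys shrinkage limits and closed forms", {
  d <- small_world(seed = 61)
  A <- build_nrm(d$pedigree)
  phen <- d$phenotypes

  ## complete-shrinkage limit: sigma_g2 -> 0 pushes EBVs to 0 and mu to ybar
  tiny <- solve_mme(phen, A, variance_components(1e-10, 1))
  expect_lt(max(abs(tiny$ebv)), 1e-6)
  expect_equal(unname(tiny$b[1]), mean(phen$value), tolerance = 1e-6)

  ## single animal, K = [1]: 2x2 closed form
  K1 <- matrix(1, 1, 1, dimnames = list("7", "7"))
  y1 <- data.frame(id = 7, value = 3.4)
  vc1 <- variance_components(2, 1)
  s1 <- solve_mme(y1, K1, vc1)
  lam <- 1 / 2
  sol_oracle <- solve(rbind(c(1, 1), c(1, 1 + lam)), c(3.4, 3.4))
  expect_equal(unname(s1$b[1]), sol_oracle[1], tolerance = 1e-10)
  expect_equal(unname(s1$ebv), sol_oracle[2], tolerance = 1e-10)
})

test_that("solve_mme solutions satisfy the Henderson equations and match GLS", {
  d <- small_world(seed = 67)
  A <- build_nrm(d$pedigree)
  phen <- d$phenotypes[sample(nrow(d$phenotypes), 60), ]
  vc <- variance_components(0.5, 0.5)
  mme <- solve_mme(phen, A, vc, method = "mme")
  gls <- solve_mme(phen, A, vc, method = "gls")
  expect_equal(mme$ebv, gls$ebv, tolerance = 1e-8)
  expect_equal(mme$b, gls$b, tolerance = 1e-8)

  ## substitute back into the mixed-model equations
  n <- nrow(A)
  pos <- match(as.character(phen$id), rownames(A))
  Zt <- matrix(0, nrow(phen), n)
  Zt[cbind(seq_len(nrow(phen)), pos)] <- 1
  X <- matrix(1, nrow(phen), 1)
  lam <- vc$sigma_e2 / vc$sigma_g2
  C <- rbind(cbind(crossprod(X), crossprod(X, Zt)),
             cbind(crossprod(Zt, X), crossprod(Zt) + solve(A) * lam))
  rhs <- c(crossprod(X, phen$value), crossprod(Zt, phen$value))
  expect_lt(max(abs(C %*% c(mme$b, mme$ebv) - rhs)), 1e-8)

  ## EBVs invariant to a constant phenotype shift; only mu moves
  phen2 <- phen
  phen2$value <- phen$value + 5
  sh <- solve_mme(phen2, A, vc)
  expect_equal(sh$ebv, mme$ebv, tolerance = 1e-8)
  expect_equal(unname(sh$b[1] - mme$b[1]), 5, tolerance = 1e-8)
})

test_that("H matrix collapses to A when G = A_gg and to G when all genotyped", {
  d <- small_world(seed = 71)
  A <- build_nrm(d$pedigree)
  gids <- rownames(d$genotypes)
  part <- partition_nrm(A, gids)
  H <- build_h_matrix(part, part$A_gg)
  ord <- rownames(H)
  expect_lt(max(abs(H - A[ord, ord])), 1e-10)

  all_part <- partition_nrm(A, rownames(A))
  G <- scale_grm(build_grm(d$genotypes_full), A)
  dimnames(G) <- dimnames(A)
  expect_equal(unname(build_h_matrix(all_part, G)), unname(G),
               tolerance = 1e-12, ignore_attr = TRUE)

  Gs <- scale_grm(build_grm(d$genotypes), part$A_gg)
  dimnames(Gs) <- list(gids, gids)
  Hs <- build_h_matrix(part, Gs)
  expect_equal(Hs, t(Hs))
  expect_gte(min(eigen(Hs, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  expect_error(build_h_matrix(part, unname(Gs)), "ID order")
})

test_that("fit_pblup delegates to solve_mme and propagates through the pedigree", {
  d <- small_world(seed = 73)
  A <- build_nrm(d$pedigree)
  vc <- variance_components(0.5, 0.5)
  phen <- d$phenotypes[d$pedigree$generation >= 2, ]
  fit <- fit_pblup(phen, A, vc)
  direct <- solve_mme(phen, A, vc)
  expect_identical(fit$ebv, direct$ebv)

  ## ancestors of phenotyped animals get nonzero EBVs; an unrelated animal
  ## with no phenotyped descendants stays at exactly zero
  ped <- as.data.frame(d$pedigree)
  parents <- unique(ped$sire[ped$generation == 2])
  expect_true(all(abs(fit$ebv[as.character(parents)]) > 1e-8))
  lone <- setdiff(ped$id[ped$generation == 0], c(ped$sire, ped$dam))
  if (length(lone)) expect_equal(max(abs(fit$ebv[as.character(lone)])), 0)

  expect_error(fit_pblup(phen[0, ], A, vc), "empty training")
  expect_error(fit_pblup(phen, A, vc, genotyped_only = TRUE), "genotyped_ids")
})

test_that("SSGBLUP with G = A_gg equals PBLUP exactly", {
  d <- small_world(seed = 79)
  A <- build_nrm(d$pedigree)
  part <- partition_nrm(A, rownames(d$genotypes))
  vc <- variance_components(0.6, 0.4)
  phen <- d$phenotypes
  pb <- fit_pblup(phen, A, vc)
  ss <- fit_ssgblup(phen, part, part$A_gg, vc, "I", scale = FALSE)
  expect_equal(ss$ebv[names(pb$ebv)], pb$ebv, tolerance = 1e-8)
})

test_that("reweighted SSGBLUP variants run and differ from variant I", {
  cfg <- sim_config(n_founders = 24, n_generations = 2,
                    matings_per_generation = 12, offspring_per_mating = 3,
                    n_snps = 200, n_chromosomes = 4, chromosome_length_bp = 5e6,
                    architecture = "major_qtl", genotyped_generations = 1:2,
                    seed = 83)
  d <- simulate_dataset(cfg)
  A <- build_nrm(d$pedigree)
  part <- partition_nrm(A, rownames(d$genotypes))
  G <- build_grm(d$genotypes)
  vc <- variance_components(d$truth$sigma_g2_true, d$truth$sigma_e2_true)
  f1 <- fit_ssgblup(d$phenotypes, part, G, vc, "I")
  f2 <- fit_ssgblup(d$phenotypes, part, G, vc, "II", genotypes = d$genotypes)
  expect_equal(sum(f2$weights), ncol(d$genotypes), tolerance = 1e-8)
  expect_gt(max(abs(f1$ebv[names(f2$ebv)] - f2$ebv)), 1e-6)
  expect_gt(cor(f1$ebv[names(f2$ebv)], f2$ebv), 0.8)
})

test_that("Gibbs variance estimation recovers heritability on simulated data", {
  cfg <- sim_config(n_founders = 60, n_generations = 2,
                    matings_per_generation = 60, offspring_per_mating = 3,
                    n_snps = 150, h2 = 0.5, genotyped_generations = 1:2,
                    seed = 89)
  d <- simulate_dataset(cfg)  # 420 animals, all phenotyped
  A <- build_nrm(d$pedigree)
  fit <- fit_pblup(d$phenotypes, A, variance_components(fixed = FALSE),
                   chain = mcmc_settings(3000, 500, 2, seed = 1))
  expect_lt(abs(fit$h2 - 0.5), 0.15)
  expect_lt(fit$psrf_sigma_g2, 1.2)
  ## posterior-mean EBVs line up with the fixed-variance solution
  ref <- fit_pblup(d$phenotypes, A,
                   variance_components(d$truth$sigma_g2_true,
                                       d$truth$sigma_e2_true))
  expect_gt(cor(fit$ebv, ref$ebv[names(fit$ebv)]), 0.98)
})

test_that("reweighted SSGBLUP holds its accuracy margin under major QTL", {
  res <- t(vapply(1:5, function(seed) {
    cfg <- sim_config(n_founders = 150, n_generations = 3,
                      matings_per_generation = 75, offspring_per_mating = 2,
                      n_snps = 600, n_chromosomes = 10,
                      chromosome_length_bp = 5e6, h2 = 0.3,
                      architecture = "major_qtl", n_qtl = 3,
                      qtl_variance_fraction = 0.2,
                      genotyped_generations = 2:3, seed = seed)
    d <- simulate_dataset(cfg)
    A <- build_nrm(d$pedigree)
    part <- partition_nrm(A, rownames(d$genotypes))
    G <- build_grm(d$genotypes)
    vc <- variance_components(d$truth$sigma_g2_true, d$truth$sigma_e2_true)
    folds <- make_cv_folds(part$A_gg, k = 5, seed = seed)
    per <- sapply(1:5, function(f) {
      val <- names(folds$fold_of)[folds$fold_of == f]
      train <- d$phenotypes[!(as.character(d$phenotypes$id) %in% val), ]
      yv <- d$phenotypes$value[match(val, as.character(d$phenotypes$id))]
      c(n = length(val),
        v1 = compute_accuracy(yv, fit_ssgblup(train, part, G, vc, "I")$ebv[val], 0.3),
        v2 = compute_accuracy(yv, fit_ssgblup(train, part, G, vc, "II",
                                              genotypes = d$genotypes)$ebv[val], 0.3))
    })
    c(v1 = pool_accuracies(per["n", ], per["v1", ]),
      v2 = pool_accuracies(per["n", ], per["v2", ]))
  }, numeric(2)))
  expect_gte(mean(res[, "v2"] - res[, "v1"]), -0.02)
})
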