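## Synthetic-data generator: multi-generation pedigrees, gene-dropped SNP
## genotypes, polygenic or few-large-QTL trait architectures, genotyping masks
## and planted pedigree/genotype conflicts. Everything downstream is testable
## against the truth objects returned here.

#' Simulation configuration
#'
#' Describes the simulated population. Defaults emulate a progeny-test beef
#' cattle design: discrete non-overlapping generations, random mating with
#' sires serving several matings, only recent generations genotyped,
#' heritability in the 0.3-0.63 range, and either a near-infinitesimal
#' (`polygenic`) trait or one with a few QTL windows jointly explaining more
#' than 15 percent of the genetic variance (`major_qtl`,
#' `qtl_variance_fraction = 0.2`).
#'
#' @param n_founders number of founder animals (generation 0); at least 2.
#' @param n_generations number of discrete offspring generations.
#' @param matings_per_generation matings per generation.
#' @param offspring_per_mating offspring per mating.
#' @param n_snps number of biallelic SNPs.
#' @param n_chromosomes number of autosomes; SNPs are split across them in
#'   contiguous blocks.
#' @param chromosome_length_bp chromosome length in base pairs.
#' @param founder_maf_range range of founder minor-allele frequencies,
#'   within (0, 0.5].
#' @param h2 narrow-sense heritability in (0, 1).
#' @param architecture `"polygenic"` or `"major_qtl"`.
#' @param n_qtl number of large QTL (architecture `"major_qtl"`).
#' @param qtl_variance_fraction fraction of genetic variance on the QTL.
#' @param genotyped_generations integer vector of generation indices whose
#'   animals are genotyped (generation 0 = founders).
#' @param seed integer seed; identical configurations reproduce identical data.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 40L,
                       n_generations = 4L,
                       matings_per_generation = 20L,
                       offspring_per_mating = 3L,
                       n_snps = 1000L,
                       n_chromosomes = 10L,
                       chromosome_length_bp = 1e8,
                       founder_maf_range = c(0.05, 0.5),
                       h2 = 0.5,
                       architecture = c("polygenic", "major_qtl"),
                       n_qtl = 3L,
                       qtl_variance_fraction = 0.2,
                       genotyped_generations = NULL,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot_scalar_prob(h2, "h2")
  if (length(founder_maf_range) != 2L || founder_maf_range[1] <= 0 ||
      founder_maf_range[2] > 0.5 || diff(founder_maf_range) < 0) {
    stop("founder_maf_range must be an increasing pair within (0, 0.5]")
  }
  if (n_founders < 2L) stop("need at least 2 founders")
  if (n_generations < 1L) stop("need at least 1 generation")
  if (architecture == "major_qtl") {
    if (n_qtl < 1L) stop("major_qtl architecture requires n_qtl >= 1")
    stopifnot_scalar_prob(qtl_variance_fraction, "qtl_variance_fraction")
  }
  if (is.null(genotyped_generations)) {
    genotyped_generations <- seq(max(1L, n_generations - 1L), n_generations)
  }
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    matings_per_generation = as.integer(matings_per_generation),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    founder_maf_range = as.numeric(founder_maf_range),
    h2 = h2,
    architecture = architecture,
    n_qtl = as.integer(n_qtl),
    qtl_variance_fraction = qtl_variance_fraction,
    genotyped_generations = as.integer(genotyped_generations),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Founders form generation 0 with alternating sexes; each later generation is
#' produced by `matings_per_generation` random matings among the previous
#' generation (one sire may serve several matings; dams are drawn without
#' replacement while possible), each yielding `offspring_per_mating` offspring
#' with alternating sexes. Records are emitted parents-first.
#'
#' @param config a [sim_config()].
#' @return a [as_pedigree()] data frame with `id, sire, dam, generation, sex`
#'   (`sex` 1 = male, 2 = female) of size
#'   `n_founders + n_generations * matings_per_generation * offspring_per_mating`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_off <- config$matings_per_generation * config$offspring_per_mating
  n_total <- config$n_founders + config$n_generations * n_off
  id <- seq_len(n_total)
  sire <- dam <- integer(n_total)
  generation <- integer(n_total)
  sex <- integer(n_total)
  sex[seq_len(config$n_founders)] <- rep_len(c(1L, 2L), config$n_founders)
  cur <- config$n_founders
  prev_ids <- seq_len(config$n_founders)
  for (g in seq_len(config$n_generations)) {
    males <- prev_ids[sex[prev_ids] == 1L]
    females <- prev_ids[sex[prev_ids] == 2L]
    if (length(males) < 1L || length(females) < 1L) {
      stop(sprintf("generation %d has no feasible matings (need >= 1 male and 1 female)", g))
    }
    sires <- sample(males, config$matings_per_generation, replace = TRUE)
    dams <- if (length(females) >= config$matings_per_generation) {
      sample(females, config$matings_per_generation, replace = FALSE)
    } else {
      sample(females, config$matings_per_generation, replace = TRUE)
    }
    new_ids <- cur + seq_len(n_off)
    sire[new_ids] <- rep(sires, each = config$offspring_per_mating)
    dam[new_ids] <- rep(dams, each = config$offspring_per_mating)
    generation[new_ids] <- g
    sex[new_ids] <- rep_len(c(1L, 2L), n_off)
    cur <- cur + n_off
    prev_ids <- new_ids
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam,
                         generation = generation, sex = sex))
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder genotypes are drawn per locus from Hardy-Weinberg proportions at a
#' frequency sampled uniformly from `founder_maf_range`; every non-founder
#' receives one allele from each parent by Mendelian transmission, loci
#' independent (no linkage). Map positions are drawn uniformly along each
#' chromosome and are strictly increasing.
#'
#' @param pedigree pedigree sorted parents-first.
#' @param config a [sim_config()].
#' @return list with `genotypes` (animals x markers 0/1/2 matrix, ID dimnames)
#'   and `map` (data frame `marker, chrom, pos_bp`).
#' @export
simulate_genotypes <- function(pedigree, config) {
  pedigree <- as_pedigree(pedigree)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p <- config$n_snps
  n <- nrow(pedigree)
  q <- runif(p, config$founder_maf_range[1], config$founder_maf_range[2])
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  codes <- matrix(0L, n, p)
  transmit <- function(parent_codes) {
    (parent_codes == 2L) + (parent_codes == 1L) * rbinom(p, 1L, 0.5)
  }
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      codes[i, ] <- rbinom(p, 2L, q)
    } else if (is.na(si[i]) || is.na(di[i])) {
      stop("pedigree mixes one known and one unknown parent; gene dropping needs both or neither")
    } else {
      codes[i, ] <- transmit(codes[si[i], ]) + transmit(codes[di[i], ])
    }
  }
  marker_ids <- sprintf("M%05d", seq_len(p))
  dimnames(codes) <- list(pedigree$id, marker_ids)
  chrom <- as.integer(cut(seq_len(p), config$n_chromosomes, labels = FALSE))
  pos <- unlist(lapply(tabulate(chrom, config$n_chromosomes), function(k) {
    sort(sample.int(config$chromosome_length_bp, k))
  }), use.names = FALSE)
  list(genotypes = codes,
       map = data.frame(marker = marker_ids, chrom = chrom, pos_bp = pos))
}

#' Simulate phenotypes with a chosen genetic architecture
#'
#' Marker effects are drawn i.i.d. normal (`polygenic`), or (`major_qtl`)
#' `n_qtl` markers in distinct 1-Mb map windows carry effects scaled so that
#' they contribute `qtl_variance_fraction` of the genetic variance, the
#' remainder spread over all other markers. True breeding values are centered
#' genotype codes times effects, rescaled so their sample variance equals the
#' target genetic variance (phenotypic variance 1, mean 10); residuals are
#' normal with variance chosen to hit `h2`.
#'
#' @param genotypes full (unmasked) genotype matrix covering every pedigree
#'   animal, as from [simulate_genotypes()].
#' @param map marker map matching `genotypes`.
#' @param pedigree the pedigree.
#' @param config a [sim_config()].
#' @param n_groups optional number of contemporary groups; when positive, a
#'   random group shift (sd `group_sd`) is added to a `raw` column so that
#'   [pre_adjust_phenotypes()] can be exercised; the `value` column stays on
#'   the adjusted scale.
#' @param group_sd standard deviation of contemporary-group shifts.
#' @return list with `phenotypes` (data frame `id, value[, raw, cg]`) and
#'   `truth` (class `"true_values"`: `tbv`, `alpha`, `qtl_idx`, `qtl_effects`,
#'   `sigma_g2_true`, `sigma_e2_true`).
#' @export
simulate_phenotypes <- function(genotypes, map, pedigree, config,
                                n_groups = 0L, group_sd = 1) {
  pedigree <- as_pedigree(pedigree)
  stopifnot(inherits(config, "sim_config"))
  if (!all(as.character(pedigree$id) %in% rownames(genotypes))) {
    stop("phenotype simulation needs the full, pre-masking genotype matrix")
  }
  set.seed(config$seed + 2L)
  G <- genotypes[as.character(pedigree$id), , drop = FALSE]
  p <- ncol(G)
  n <- nrow(G)
  Tm <- sweep(G, 2L, colMeans(G))
  var_p <- 1
  sg2 <- config$h2 * var_p
  se2 <- var_p - sg2
  qtl_idx <- integer(0)
  qtl_effects <- numeric(0)
  if (config$architecture == "polygenic") {
    alpha <- rnorm(p)
    tbv <- drop(Tm %*% alpha)
    sc <- sqrt(sg2 / var(tbv))
    alpha <- alpha * sc
    tbv <- tbv * sc
  } else {
    win <- paste(map$chrom, floor(map$pos_bp / 1e6), sep = ":")
    uw <- unique(win)
    if (config$n_qtl > length(uw)) {
      stop(sprintf("requested %d QTL but only %d distinct 1-Mb windows exist",
                   config$n_qtl, length(uw)))
    }
    qtl_win <- sample(uw, config$n_qtl)
    qtl_idx <- vapply(qtl_win, function(w) sample(which(win == w), 1L), 1L)
    qtl_idx <- unname(sort(qtl_idx))
    bg_idx <- setdiff(seq_len(p), qtl_idx)
    ## equal per-QTL variance contributions, then one joint rescale so the
    ## QTL block explains exactly the configured fraction
    a_q <- sample(c(-1, 1), config$n_qtl, replace = TRUE) /
      apply(Tm[, qtl_idx, drop = FALSE], 2L, sd)
    g_q <- drop(Tm[, qtl_idx, drop = FALSE] %*% a_q)
    a_q <- a_q * sqrt(config$qtl_variance_fraction * sg2 / var(g_q))
    g_q <- drop(Tm[, qtl_idx, drop = FALSE] %*% a_q)
    a_b <- rnorm(length(bg_idx))
    g_b <- drop(Tm[, bg_idx, drop = FALSE] %*% a_b)
    a_b <- a_b * sqrt((1 - config$qtl_variance_fraction) * sg2 / var(g_b))
    g_b <- drop(Tm[, bg_idx, drop = FALSE] %*% a_b)
    alpha <- numeric(p)
    alpha[qtl_idx] <- a_q
    alpha[bg_idx] <- a_b
    qtl_effects <- a_q
    tbv <- g_q + g_b
  }
  y <- 10 + tbv + rnorm(n, 0, sqrt(se2))
  phen <- data.frame(id = pedigree$id, value = y)
  if (n_groups > 0L) {
    cg <- sample.int(n_groups, n, replace = TRUE)
    shift <- rnorm(n_groups, 0, group_sd)
    phen$raw <- y + shift[cg]
    phen$cg <- cg
  }
  truth <- list(tbv = setNames(tbv, pedigree$id), alpha = alpha,
                qtl_idx = qtl_idx, qtl_effects = qtl_effects,
                sigma_g2_true = var(tbv), sigma_e2_true = se2)
  class(truth) <- "true_values"
  list(phenotypes = phen, truth = truth)
}

#' Restrict genotypes to the genotyped generations
#'
#' Masked animals keep their pedigree links and phenotypes; only their
#' genotype rows are dropped, creating the genotyped/non-genotyped split that
#' single-step methods exploit.
#'
#' @inheritParams simulate_phenotypes
#' @return the genotype submatrix for animals whose generation is in
#'   `config$genotyped_generations`.
#' @export
mask_genotypes <- function(genotypes, pedigree, config) {
  pedigree <- as_pedigree(pedigree)
  stopifnot(inherits(config, "sim_config"))
  if (length(config$genotyped_generations) == 0L) {
    stop("genotyped_generations must be non-empty")
  }
  keep <- pedigree$id[pedigree$generation %in% config$genotyped_generations]
  if (length(keep) == 0L) stop("masking left no genotyped animals")
  genotypes[as.character(keep), , drop = FALSE]
}

#' Plant genotype/pedigree conflicts
#'
#' Emulates the data errors a relationship-based screen must catch:
#' `n_duplicates` animals are re-entered under a new ID recorded as an
#' unrelated founder but carrying an identical genotype row, and
#' `n_parentage_errors` genotyped offspring have their recorded sire swapped
#' for an unrelated animal of the same generation. The returned record lists
#' every planted error so tests can check recovery by [detect_conflicts()];
#' for a parentage swap the detectable pairs are the induced half-sib pairs
#' (recorded 0.25 with genomic near 0, or recorded 0 with genomic near 0.25).
#'
#' @param genotypes genotype matrix of the genotyped animals.
#' @param pedigree the pedigree.
#' @param n_duplicates number of duplicate-ID errors to plant.
#' @param n_parentage_errors number of sire swaps to plant.
#' @param seed integer seed.
#' @return list with modified `genotypes`, `pedigree`, and `errors` (a data
#'   frame `type, id, counterpart, new_parent`).
#' @export
plant_conflicts <- function(genotypes, pedigree, n_duplicates = 0L,
                            n_parentage_errors = 0L, seed = 1L) {
  pedigree <- as_pedigree(pedigree)
  set.seed(seed)
  gids <- rownames(genotypes)
  if (n_duplicates + n_parentage_errors > length(gids)) {
    stop("more planted errors than genotyped animals")
  }
  if (n_duplicates == 0L && n_parentage_errors == 0L) {
    return(list(genotypes = genotypes, pedigree = pedigree,
                errors = data.frame(type = character(0), id = integer(0),
                                    counterpart = integer(0),
                                    new_parent = integer(0))))
  }
  errors <- list()
  ped <- as.data.frame(pedigree)
  if (n_duplicates > 0L) {
    src <- sample(gids, n_duplicates)
    for (s in src) {
      new_id <- max(ped$id) + 1L
      row <- ped[ped$id == as.integer(s), ]
      ped <- rbind(ped, data.frame(id = new_id, sire = 0L, dam = 0L,
                                   generation = row$generation,
                                   sex = row$sex))
      genotypes <- rbind(genotypes, genotypes[s, , drop = FALSE])
      rownames(genotypes)[nrow(genotypes)] <- new_id
      errors[[length(errors) + 1L]] <-
        data.frame(type = "duplicate", id = new_id,
                   counterpart = as.integer(s), new_parent = NA_integer_)
    }
  }
  if (n_parentage_errors > 0L) {
    A <- build_nrm(as_pedigree(ped))
    sire_kids <- table(ped$sire[ped$sire != 0L])
    used <- integer(0)
    planted <- 0L
    ## children must be genotyped, have genotyped half-sibs through the true
    ## sire, and a same-generation unrelated replacement sire with genotyped
    ## offspring must exist -- otherwise the swap is undetectable in G vs A
    cand <- ped$id[ped$sire != 0L & ped$id %in% as.integer(gids) &
                     ped$sire %in% as.integer(names(sire_kids[sire_kids >= 2L]))]
    for (child in sample(cand)) {
      if (planted >= n_parentage_errors) break
      if (child %in% used) next
      crow <- ped$id == child
      old_sire <- ped$sire[crow]
      sibs <- ped$id[ped$sire == old_sire & ped$id != child]
      if (!any(as.character(sibs) %in% gids)) next
      gen_s <- ped$generation[ped$id == old_sire]
      repl_pool <- ped$id[ped$generation == gen_s & ped$sex == 1L &
                            ped$id != old_sire]
      repl_pool <- repl_pool[A[as.character(child), as.character(repl_pool)] == 0]
      repl_pool <- repl_pool[vapply(repl_pool, function(r) {
        kids <- ped$id[ped$sire == r]
        any(as.character(kids) %in% gids)
      }, logical(1))]
      if (length(repl_pool) == 0L) next
      new_sire <- if (length(repl_pool) == 1L) repl_pool else sample(repl_pool, 1L)
      ped$sire[crow] <- new_sire
      used <- c(used, child)
      planted <- planted + 1L
      errors[[length(errors) + 1L]] <-
        data.frame(type = "parentage", id = child, counterpart = old_sire,
                   new_parent = new_sire)
    }
    if (planted < n_parentage_errors) {
      stop("could not plant the requested number of detectable parentage errors")
    }
  }
  list(genotypes = genotypes, pedigree = as_pedigree(ped),
       errors = do.call(rbind, errors))
}

#' Simulate a complete analysis-ready data set
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_phenotypes()] and [mask_genotypes()] for one configuration.
#'
#' @param config a [sim_config()].
#' @param ... passed to [simulate_phenotypes()].
#' @return list with `config`, `pedigree`, `genotypes_full`, `genotypes`
#'   (masked), `map`, `phenotypes`, `truth`.
#' @export
simulate_dataset <- function(config, ...) {
  ped <- simulate_pedigree(config)
  gd <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(gd$genotypes, gd$map, ped, config, ...)
  list(config = config, pedigree = ped, genotypes_full = gd$genotypes,
       genotypes = mask_genotypes(gd$genotypes, ped, config), map = gd$map,
       phenotypes = ph$phenotypes, truth = ph$truth)
}
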