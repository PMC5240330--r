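## Independent oracles and small fixtures shared across tests.

## Wright's path-counting relationship coefficients, implemented without the
## tabular recursion: enumerate all ancestor chains of each animal, pair
## chains meeting in a common ancestor with otherwise disjoint members, and
## sum (1/2)^(links) * (1 + F_ancestor). Exponential, fine for toy pedigrees.
wright_nrm <- function(ped) {
  ids <- ped$id
  sire <- setNames(ped$sire, ids)
  dam <- setNames(ped$dam, ids)
  chains_up <- function(i) {
    out <- list(c(i))
    for (p in c(sire[[as.character(i)]], dam[[as.character(i)]])) {
      if (p != 0L) out <- c(out, lapply(chains_up(p), function(ch) c(i, ch)))
    }
    out
  }
  F_of <- function(i) {
    s <- sire[[as.character(i)]]
    d <- dam[[as.character(i)]]
    if (s == 0L || d == 0L) return(0)
    a_pair(s, d) / 2
  }
  a_pair <- function(i, j) {
    if (i == j) return(1 + F_of(i))
    ci <- chains_up(i)
    cj <- chains_up(j)
    tot <- 0
    for (p1 in ci) {
      for (p2 in cj) {
        anc <- p1[length(p1)]
        if (anc != p2[length(p2)]) next
        if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0L) next
        tot <- tot + 0.5^(length(p1) - 1L + length(p2) - 1L) * (1 + F_of(anc))
      }
    }
    tot
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in a:n) A[a, b] <- A[b, a] <- a_pair(ids[a], ids[b])
  }
  A
}

## Gene-dropping identity-by-descent oracle: drop unique founder alleles
## through the pedigree n_rep times; the estimated additive relationship is
## twice the average fraction of matching allele pairs. Returns the estimate
## and its Monte-Carlo standard error for requested id pairs.
genedrop_relationship <- function(ped, pairs, n_rep = 4000L, seed = 1L) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  a1 <- matrix(0L, n, n_rep)
  a2 <- matrix(0L, n, n_rep)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      a1[i, ] <- next_allele + 1L
      a2[i, ] <- next_allele + 2L
      next_allele <- next_allele + 2L
    } else {
      pick1 <- runif(n_rep) < 0.5
      a1[i, ] <- ifelse(pick1, a1[si[i], ], a2[si[i], ])
      pick2 <- runif(n_rep) < 0.5
      a2[i, ] <- ifelse(pick2, a1[di[i], ], a2[di[i], ])
    }
  }
  t(vapply(seq_len(nrow(pairs)), function(r) {
    i <- match(pairs[r, 1L], ped$id)
    j <- match(pairs[r, 2L], ped$id)
    share <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
             (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
    est <- share / 2  # 2 * kinship per replicate
    c(mean(est), sd(est) / sqrt(n_rep))
  }, numeric(2)))
}

## textbook toy pedigrees (id, sire, dam), parents-first
toy_pedigrees <- function() {
  list(
    parent_offspring = data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2)),
    full_sibs = data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2)),
    half_sibs = data.frame(id = 1:5, sire = c(0, 0, 0, 1, 1),
                           dam = c(0, 0, 0, 2, 3)),
    full_sib_mating = data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                                 dam = c(0, 0, 2, 2, 4)),
    parent_offspring_mating = data.frame(id = 1:4, sire = c(0, 0, 1, 1),
                                         dam = c(0, 0, 2, 3)),
    three_generations = data.frame(id = 1:6, sire = c(0, 0, 1, 0, 3, 3),
                                   dam = c(0, 0, 2, 0, 4, 4)),
    half_sib_mating = data.frame(id = 1:6, sire = c(0, 0, 0, 1, 1, 4),
                                 dam = c(0, 0, 0, 2, 3, 5)),
    backcross = data.frame(id = 1:5, sire = c(0, 0, 1, 3, 0),
                           dam = c(0, 0, 2, 2, 0)),
    double_grandparent = data.frame(id = 1:6, sire = c(0, 0, 1, 1, 3, 4),
                                    dam = c(0, 0, 2, 2, 2, 5))
  )
}

## a small simulated world used by several tests
small_world <- function(seed = 7, ...) {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    matings_per_generation = 10, offspring_per_mating = 3,
                    n_snps = 200, n_chromosomes = 4,
                    chromosome_length_bp = 5e6,
                    genotyped_generations = c(2, 3), seed = seed, ...)
  simulate_dataset(cfg)
}

quick_chain <- function(n_iter = 1500L, burn_in = 300L, thin = 2L, seed = 42L) {
  mcmc_settings(n_iter, burn_in, thin, seed)
}
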