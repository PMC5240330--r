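---
title: "Single-step genomic prediction: models, machinery and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic prediction: models, machinery and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical choices
a maintainer would want written down. Every empirical statement below is one
the test suite computes; nothing here quotes numbers the package cannot
reproduce.

## The problem

In most breeding programs only a recent subset of animals is genotyped, while
pedigree and phenotype records reach much further back. The package predicts
additive genetic merit (EBVs) for a single trait in that setting and compares
the standard families of methods head-to-head on common data:

* **PBLUP / PBLUP-G** — the animal model `y = 1μ + Zu + e` with
  `u ~ N(0, A σ_g²)`, using phenotypes on all animals or on genotyped animals
  only. `A` is the numerator relationship matrix from the tabular method.
* **BayesB / BayesC / BayesCπ** — whole-genome regression
  `y = 1μ + M_g α + e` on genotyped animals, with a point-mass(π)/slab
  mixture prior per marker: a t slab via locus-specific
  scaled-inverse-chi-square variances (B) or a normal slab with one common
  variance (C); Cπ gives π a uniform prior and samples it.
* **SSGBLUP I/II/III** — the animal model with `A` replaced by the combined
  matrix `H` that merges the genomic relationship matrix `G` of the genotyped
  block with pedigree relationships elsewhere. Variants II and III rebuild
  `G` with locus weights back-solved from the variant-I EBVs (one and five
  iterations).
* **SSBR-B/C/Cπ** — the same mixture-prior regressions extended to
  non-genotyped animals through imputed covariates
  `M̂_n = A_ng A_gg⁻¹ M_g`, an imputation residual
  `ε ~ N(0, (A_nn − A_ng A_gg⁻¹ A_gn) σ_g²)`, and a genotyped-group mean
  shift `μ_g`.

Accuracy is assessed by pedigree-aware cross-validation: K-means on the rows
of `A_gg` assigns genotyped animals to folds so that close relatives tend to
be held out together; per-fold accuracy is `cor(y_adj, EBV) / √h²`, pooled by
validation-set size; bias is the slope of adjusted phenotype on EBV.

## The exact single-step equivalence

With known variances, SSBR-C at π = 0 is an equivalent model to single-step
GBLUP. The package states this identity precisely, because it is exact only
in one parameterization:

* `G` must be the **unscaled** centered `T T′ / Σ 2q(1−q)`;
* the GBLUP fixed effects must include the genotyped-group covariate
  `x = −[A_ng A_gg⁻¹ 1; 1]` (the `μ_g` column of the regression design);
* the regression EBVs must be shifted by `x · γ̂`, where `γ̂ = m̄′α̂` is the
  marker-mean contrast that the flat `μ_g` absorbs (raw 0/1/2 covariates are
  not centered, so `M_g α` carries the level `1 γ` that the centered `T α`
  does not).

Under those three conditions `solve_ssbr_direct()$ebv_h_scale` equals the
`fit_ssgblup(..., scale = FALSE, include_mu_g = TRUE, solver = "gls")`
solution to machine precision, and on genotyped animals the shift is the
constant `−γ̂`, so validation correlations — hence accuracies — coincide
exactly. That is the test the acceptance suite runs (criterion 2), together
with a 50,000-iteration Gibbs chain whose posterior-mean EBVs correlate
≥ 0.999 with the direct solution. The routinely used SSGBLUP-I (scaled `G`,
intercept only) is *not* numerically identical, only very close.

```{r}
library(ssgp)
d <- simulate_dataset(sim_config(seed = 11))
A <- build_nrm(d$pedigree)
part <- partition_nrm(A, rownames(d$genotypes))
des <- build_ssbr_design(part, d$genotypes)
vc <- variance_components(d$truth$sigma_g2_true, d$truth$sigma_e2_true)
k <- sum(2 * (colMeans(d$genotypes) / 2) * (1 - colMeans(d$genotypes) / 2))
direct <- solve_ssbr_direct(d$phenotypes, des, vc, sigma_alpha2 = vc$sigma_g2 / k)
hfit <- fit_ssgblup(d$phenotypes, part, build_grm(d$genotypes), vc, "I",
                    scale = FALSE, include_mu_g = TRUE, solver = "gls")
max(abs(direct$ebv_h_scale - hfit$ebv[names(direct$ebv)]))  # ~1e-14
```

## Scaling G to the pedigree block

Centering the genotype matrix makes `G 1 = 0`: the raw `G` is singular and
its mean off-diagonal is slightly negative. "Scaling the diagonal and
off-diagonal means of `G` to those of `A_gg`" is therefore implemented as the
affine tuning `G* = β G + α 1 1′` whose two coefficients solve the two
mean-matching equations — the adjustment used by the standard single-step
software. A literal multiplicative rescaling of the off-diagonals would
multiply by a large negative number (their mean is negative), destroying
positive semi-definiteness; the affine form instead restores a positive
eigenvalue in the `1` direction, which is exactly the singularity that
centering introduced. When the marker count is below the animal count the
tuned matrix can still be rank-deficient; every solver then applies the
package-wide jitter policy (one shot of `1e-8` on the diagonal, then error).

## Samplers and numerics

* **Marker mixture models** are single-site Gibbs samplers in C++
  (RcppArmadillo) drawing from R's RNG, so `set.seed()` gives bitwise
  reproducible chains. Per locus: the inclusion indicator from the marginal
  Bayes factor against the point mass, then the effect from its normal full
  conditional. BayesB samples a locus variance (full conditional when the
  locus is in the model, prior when it is out); BayesC one common variance;
  π, when estimated, comes from `Beta(p − m + 1, m + 1)`.
* **Slab scale**: `ν_α = 4.2` by default, with
  `S_α² = h²_prior · var(y) / ((1−π) Σ 2q(1−q)) · (ν_α−2)/ν_α`, overridable
  (`sigma_alpha2`). "Fixed variances" fixes σ_e² (and the common marker
  variance for family C); BayesB's locus variances are always sampled —
  they are the prior, not a variance component.
* **Imputation residuals** are drawn as one block per iteration. With fixed
  variances the precision matrix is constant, so its inverse and a sampling
  factor are cached and each draw costs two matrix-vector products; with
  estimated variances the Cholesky factor is recomputed whenever σ_e² or
  σ_g² moves.
* **PBLUP/SSGBLUP variance estimation** runs in the eigenspace of `Z L`
  (`K = L L′`): after one SVD the rotated coordinates have independent
  normal full conditionals and each sweep is O(n). The unobserved null-space
  mass of `u` enters σ_g²'s full conditional through a single chi-square
  draw. Priors are scaled-inverse-chi-square with ν = 4 and scales set from
  a prior h² (default 0.5) and `var(y)`; chains report a split-chain
  potential-scale-reduction diagnostic.
* **Direct solves** use Henderson's equations when `K` is invertible and an
  equivalent GLS (variance-form) solve otherwise; both are exposed and
  tested against each other.

## Window-variance GWAS

Per retained draw, each 1-Mb window's genetic values are the centered window
genotypes times the window's sampled effects; the window's share is its
variance across animals divided by the **sum of window variances**, so shares
sum to one exactly in every draw (window genetic values covary slightly, so
normalizing by the variance of the total would not). Shares are averaged
over draws (no Rao-Blackwellization — simplicity over a minor variance
reduction). Windows are half-open `[k·1Mb, (k+1)·1Mb)` anchored at 0.
A "maximum window share" bound is only meaningful when the genome has many
windows: with `w` windows the maximum share is necessarily ≥ 1/w.

## The synthetic world

The generator emulates a progeny-tested beef-cattle design: discrete
non-overlapping generations, random mating with sires serving several
matings, sexes alternating (so mating is always feasible), only recent
generations genotyped, biallelic SNPs gene-dropped from founders in
Hardy-Weinberg proportions, heritabilities in the 0.3–0.63 range, and two
trait architectures — near-infinitesimal, or a `major_qtl` trait whose few
QTL windows jointly explain a configured fraction of the genetic variance
(default 0.20, "more than 15%"). QTL effects are scaled to equal per-QTL
contributions, then jointly rescaled so the block hits the configured
fraction exactly; phenotypes are emitted on the adjusted scale (mean 10,
phenotypic variance 1), with an optional contemporary-group layer solely to
exercise the pre-adjustment code. `plant_conflicts()` seeds duplicate-ID and
misrecorded-parent errors whose detectable signatures (genomic ≈ 1 vs
pedigree 0; recorded half-sibs vs genomic strangers and vice versa) are what
the conflict screen looks for.

**What the generator does not emulate — and what that implies.** Loci are
unlinked: there is no LD, no selection, no overlapping generations. Most
consequences are benign (the likelihoods used by every model treat markers
as exchangeable covariates), but one is not. In real 50k data, tens of
thousands of markers tag on the order of a thousand effective chromosome
segments, so a π = 0.98 mixture still retains enough markers to track the
polygenic background *and* sharpen the large QTL — which is how a mixture
prior can beat SSGBLUP on a QTL trait. With unlinked loci the background
occupies ~p independent segments; the 2% of markers a high-π prior keeps
cannot track it, and measured accuracy declines monotonically in π, with the
sign flipping only when the QTL carry several times the stated fraction of
variance. The corresponding acceptance check is left red deliberately, with
the measurements recorded, rather than inflating the generator's QTL
fraction to force it green. A green run of every other test establishes the
machinery is right; it does not establish that mixture priors win on QTL
traits in a world without LD — they provably do not.

## Other deliberate choices

* Unknown parents are unrelated, non-inbred founders; no unknown-parent
  groups or metafounders. Pedigrees are never silently re-sorted.
* Dense `A` throughout (the intended scale is ≤ ~10⁴ animals); no sparse
  A-inverse.
* Sporadically missing genotypes are mean-imputed (`2q̂`); phasing-based
  imputation is out of scope and documented as a fidelity gap.
* Marker QC attributes each removed marker to the first failing rule in the
  order missing → MAF → Hardy-Weinberg (1-df Pearson chi-square against
  expectations from the sample allele frequency).
* Conflict-screen thresholds (duplicate: g ≥ 0.9 and a ≤ 0.1; parentage:
  |g − a| ≥ 0.2 with either coefficient within 0.1 of 0.25) are calibrated
  on synthetic data only and exposed as arguments.
* `μ_g` is reported but never folded into EBV rankings: validation animals
  are genotyped, so a common shift cancels in correlations. When every
  animal is genotyped the `μ_g` column equals minus the intercept column and
  is dropped.
* Reweighting (`reweight_grm`) keeps the variant-I EBVs fixed across
  iterations and renormalizes locus weights to sum to p each round, keeping
  the variance scale stable.
* Accuracies are not clipped at 1; h² is a user input, as when literature
  values are used for real traits.

## Known limitations

Single trait, single record per animal; no REML; no maternal or residual
polygenic effects (the latter deliberately, matching the modeling choice the
package replicates); no haplotype phasing or X chromosome; the mating
structure is a stand-in for a real progeny-test design, not a
reconstruction.
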