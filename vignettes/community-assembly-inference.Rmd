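---
title: "Simulating community assembly and detecting the footprint of selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating community assembly and detecting the footprint of selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`assemblage` implements an individual-based, zero-sum (Moran) model of local
community assembly coupled to a fixed regional species pool.  A local
community holds exactly `J` individuals.  At every time step one individual
dies and is replaced: with probability `m` by an immigrant drawn from the
metacommunity in proportion to regional abundance, otherwise by the offspring
of a uniformly chosen surviving individual, which with probability `nu`
founds a new species by point mutation (its trait is the parent trait plus a
`Normal(0, sigma_sp)` perturbation).  One generation is defined as `J`
death-birth events.  Selection acts on the death event only; the birth side
is always neutral.

Each species carries a single trait value `z` shared by all conspecifics
(intraspecific variation is assumed negligible against interspecific
variation).  Five death models are available.  Writing `q_i` for the
unnormalized death rate of individual `i` (the death probability is
`q_i / sum_j q_j`):

* **neutral** — `q_i = 1`, so every individual dies with probability `1/J`;
* **filtering** — `q_i = 1 - exp(-s_E (z_i - z_E)^2)`: distance from an
  environmental optimum `z_E` is penalized;
* **mean** (mean-field competition) — `q_i = exp(-s_E (z_i - zbar)^2)` with
  `zbar` the current community mean trait;
* **pairwise** — `q_i = sum_{j != i} exp(-s_E (z_i - z_j)^2)`: every other
  individual competes with strength decaying in trait distance;
* **beta** — as pairwise, with each term weighted `beta_intra` for
  conspecific and `beta_inter` for heterospecific pairs, modelling negative
  density dependence.  The `beta_intra < beta_inter` regime collapses to
  monodominance and is rejected at parameter validation.

For the mean, pairwise and equal-beta kernels the death field converges to
the uniform `1/J` exactly as `s_E -> 0`, so the models form a continuum from
neutrality to strong selection.  With unequal betas the `s_E = 0` limit is
*not* neutral — the rate `beta_intra (n_a - 1) + beta_inter (J - n_a)`
retains pure density dependence — so the neutral-limit property is only
asserted for equal weights.

Because conspecifics share a trait, the pairwise/beta rate of any member of
species `a` collapses to the species-aggregated form

```
q(a) = beta_intra (n_a - 1) + beta_inter * sum_{b != a} n_b exp(-s_E (z_a - z_b)^2)
```

which costs `O(S^2)` in species rather than `O(J^2)` in individuals.  The
compiled event loop maintains these sums incrementally in `O(S)` per event
and refreshes them in full once per generation to bound floating-point
drift; the R function `aggregated_pairwise_rates()` exposes the same
quantity and is tested against a literal `O(J^2)` double loop at `1e-10`.

### Progress toward equilibrium

`lambda` is the proportion of individuals descending from a lineage that
colonized (immigrated or speciated) after the start of the simulation.  It
is 0 at the founding state and 1 once no descendant of the founding
population remains, at which point the initial conditions are undetectable.
Runs stop when `lambda` reaches `lambda_target` (checked at generation
boundaries) or at a hard generation cap, in which case they return a
truncation flag rather than an error.

### Initialization

The starting state is not fixed by the model description; here all `J`
individuals initially belong to a single founder species drawn from the
metacommunity abundance-weighted.  `lambda` then measures the replacement of
that founding population, matching its definition as the fraction of
post-founding lineages.

## The metacommunity

The regional pool is fixed on the timescale of local assembly.  Its
generator is a modelling choice: relative abundances follow a Fisher
log-series (shape 0.98 by default), and traits evolve by Brownian motion
(rate 1) along a Yule tree over the pool's species, giving them the
phylogenetic clustering real regional floras and faunas show; `iid_normal`
traits are available as a cheaper alternative.  The reference trait mean and
SD are abundance-weighted because the local community samples individuals,
not species.  The filtering optimum `z_E` defaults to the regional trait
mean and can be overridden to study mismatch.

## The genetic axis

After the forward simulation, each extant species' recorded abundance
trajectory constrains a backward-time Hudson coalescent: the haploid
effective size is `Ne(t) = alpha * abundance(t)` as a piecewise-constant
step function at the trajectory's recording resolution, and lineages older
than the species' colonization coalesce in a panmictic source pool
(default `1e5`) standing in for the regional metapopulation, for which the
model prescribes no genetic structure.  Mutations follow an infinite-sites
model on a single non-recombining locus; defaults (570 bp, 10 haplotypes,
`mu = 1e-7` per site per generation) emulate the small mtDNA surveys
(COI barcodes) typical of the empirical community datasets this kind of
analysis targets.  Nucleotide diversity `pi` is the mean pairwise
difference per site; with constant `Ne` its expectation is the haploid
`theta = 2 Ne mu`, which anchors the module's correctness tests, together
with a bottleneck-depression check and the `c*Ne, mu/c` scaling identity.

## Summary statistics

Each simulation (or empirical-style dataset) reduces to a fixed-order
feature vector over three data axes — species abundances, per-species
genetic diversity, species trait values:

* richness `S`;
* first four moments per axis (abundance moments on the log scale, the
  conventional scale for abundance distributions; trait and genetic moments
  species-weighted);
* Hill numbers of orders 1–4 per axis.  Abundance Hill numbers are the
  classic effective species numbers; genetic Hill numbers apply the same
  formula to diversities normalized to proportions across species; trait
  Hill numbers are Chiu–Chao functional (attribute-diversity) Hill numbers
  with pairwise distances normalized by Rao's Q, making them invariant to
  trait rescaling;
* Spearman rank correlations between every pair of axes;
* abundance-weighted local-minus-regional trait mean and SD.

Undefined entries (moments of too-few species, zero-distance trait sets,
all-zero diversities, masked axes) carry an explicit `NA` sentinel and are
never silently zeroed.  `lambda` rides along as metadata but is never a
classifier feature, because empirical communities do not expose their
equilibrium progress.

## Inference

A random forest (1000 trees, default mtry/depth, tree-vote class
probabilities, fixed seed, single-threaded for reproducibility) is trained
on labelled simulations under one of three axis masks mirroring what
empirical datasets provide: abundance+genetic, trait+genetic, or all three.
Accuracy is estimated by stratified 5-fold cross-validation pooled into a
single confusion matrix; a collapsed accuracy additionally merges the
pairwise and beta competition classes, which are mechanistically the most
similar pair and the classifier's dominant confusion.  Under a mask,
all-sentinel columns are dropped (never imputed), as are the rare rows with
sporadic sentinels.  `pca_projection()` gives the column-standardized PCA
view used to inspect how the model classes separate as `lambda` grows.

## Priors and batch experiments

`experiment_config()` fixes the study conditions for batch simulation:
`J ~ U{500..2000}`, `s_E ~ logU[0.001, 1]`, `m ~ logU[1e-4, 1e-2]`,
`nu = 0` with probability 1/3 otherwise `logU[1e-4, 5e-3]`,
`beta_intra/beta_inter ~ logU[1, 30]` with `beta_inter = 1`,
`alpha ~ logU[100, 1e4]`, `lambda_target ~ U{0.25, 0.5, 0.75, 1}`.  Every
run's seed derives deterministically from the master seed and run index, and
every batch persists its configuration and realized draw table, so batches
are exactly reproducible and resumable.

Trajectory recording defaults to every generation; batch runs thin the
cadence so each species history has on the order of 500 coalescent epochs,
which keeps the piecewise-constant `Ne` faithful to the recorded abundance
fluctuations while bounding memory.

### Problem sizes used by the shipped checks

The package's acceptance checks run a scaled version of the full protocol:
500 simulations per model (2,500 total) with `J` restricted to
`[500, 1000]`, cross-validated under all three axis masks with a shuffled-
label baseline; a 30-replicate-per-model trait-signature suite at
`J = 1000`, `s_E = 0.1`, `m = 5e-3`, `nu = 0` run to `lambda = 1`
(`beta_intra = 10` for the beta model); and 2,000-replicate coalescent
anchors.  These sizes are the package's chosen desk-scale study conditions;
the full-scale protocol (10,000 simulations per model) is a matter of
compute, not of code, and `classification_experiment()` exposes the scale
as an argument.

## Numerical choices

* Exponent arguments are clamped at -700 before exponentiation; smaller
  contributions are treated as zero.
* An all-zero death-rate vector (e.g. filtering with every individual at
  the optimum) is completed as the uniform field with a logged warning,
  the `s_E -> 0`-consistent choice, rather than an error.
* The community mean trait used by the mean kernel is recomputed before
  drawing each death index.
* Species-level caches are refreshed in full every generation; the
  incremental updates alone are exact in real arithmetic, so the refresh
  only bounds floating-point drift.
* Ties and degenerate inputs in the summary statistics resolve to `NA`
  sentinels, documented above.

## What the generator does and does not emulate

The synthetic batches vary community age, size, selection strength,
immigration, speciation and genetic scaling over wide ranges, which is what
gives the classifier something to learn.  They do **not** emulate several
features of real data: observational sampling error (abundances are true
counts, not survey estimates), intraspecific trait variation, multilocus or
recombining sequence data, spatial structure within the local community,
or a metacommunity with its own genetic structure.  Passing checks on
synthetic data therefore demonstrate that the inference machinery recovers
the generating process *of this model family*, not that any particular
empirical community was assembled by one of these five processes.

## Known limitations

* At moderate selection (`s_E ~ 0.1`) the pairwise kernel's width
  `1/sqrt(s_E)` spans a large fraction of the occupied trait range, so the
  model organizes abundance into a few evenly spaced niches each shared by
  several near-identical-trait species (the kernel is nearly flat at small
  distances, making within-niche coexistence near-neutral).  Species-level
  nearest-gap statistics therefore show little regularization even when
  niche-level spacing is strongly regular; the trait axis carries the
  competition signal mostly through its variance and band-occupancy
  statistics.
* The `beta_intra < beta_inter` regime, selection on births, species-pair-
  specific interaction matrices and multidimensional traits are out of
  scope.
* The coalescent treats each species independently; no migration-coalescent
  couples local and regional genealogies beyond the source-pool completion.
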