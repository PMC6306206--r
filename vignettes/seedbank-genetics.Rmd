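---
title: "Dominant-marker population genetics of aboveground and seed-bank cohorts"
author: "aflpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker population genetics of aboveground and seed-bank cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpop)
```

## The scientific problem

Persistent soil seed banks store the offspring of several past aboveground
generations. Whether they also store genetic diversity — and so buffer
populations against drift, selection and disturbance — is best asked by
genotyping paired cohorts: standing plants (AG) and seedlings germinated
from soil cores (SB), across populations that differ in their selection
regime (e.g. open meadow vs shaded woodland along a successional gradient).

AFLP markers are the workhorse for such surveys in non-model plants. They
are *dominant*: one observes only the band phenotype (1 = band present,
0 = absent), and a band-present plant may be homozygous or heterozygous for
the band allele. `aflpop` therefore analyses the binary phenotype matrix
directly, and only introduces allele frequencies where an explicit
inbreeding model makes them identifiable (the kinship estimator below).

This vignette documents the models, the estimators, their assumptions, the
numerical choices, and what the simulation-based tests do and do not show.

## Data model and locus filtering

A `marker_matrix` is a complete 0/1 matrix (individuals × loci); missing
values are rejected rather than imputed, because AFLP scoring produces
complete calls and silent imputation would bias band frequencies. The
`sample_table` carries population, region, habitat, cohort, 1-m grid
coordinates, and (for SB samples) the germination tray and its two pooled
source cells.

`filter_loci()` removes loci that are monomorphic or deviate in a single
individual: a one-individual deviation is indistinguishable from a scoring
artefact at typical AFLP error rates (~0.5–1%), and such loci would
contribute pure noise to every downstream statistic. The rule is applied
over the pooled dataset by default, matching single-batch scoring; a
`scope_groups` argument restricts it per group for multi-batch designs.
`replicate_error_rate()` is the plain mismatch fraction over replicate
pairs × loci; the locus set is whatever matrix is passed, so both
pre-filter and post-filter rates are available (the published convention
does not specify which; we default to documenting both rather than
asserting one).

## Rarefied diversity

All diversity measures are hypergeometric expectations at a common
rarefaction size $g$ (default 12, the smallest cohort in the motivating
survey), which removes the bias from unequal cohort sizes:

* **Band richness** per locus with $n_1$ band-present of $N$:
  $Br = [1 - \binom{N-n_1}{g}/\binom{N}{g}] + [1 - \binom{N-n_0}{g}/\binom{N}{g}]$,
  averaged over loci; it lies in $[1, 2]$.
* **Private band richness** between paired cohorts: with detection
  probabilities $Q_c = 1 - \binom{N_c-n_{1c}}{g}/\binom{N_c}{g}$,
  $PBr_a = \sum_\ell Q_a (1 - Q_b)$. Only the band-presence state counts as
  a band: the absence state is not a fragment and cannot be "private".
  Note two properties that are sometimes assumed but do **not** hold:
  $PBr$ of two identical groups is positive below $g = N$ (each group can
  miss the band the other detects), and $PBr$ is not monotone in $g$ (a
  band fixed in one group and rare in the other contributes
  $(N-g)/N$, which falls as $g$ grows). The test suite asserts the true
  properties (symmetry; zero at $g = N$; Monte-Carlo agreement).
* **Multilocus phenotype richness**: grouping rows into identical
  phenotypes with counts $N_i$,
  $eMLG = \sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$ and
  $P_u = (eMLG - 1)/(g - 1)$, so $P_u$ equals the conventional
  $(eMLG-1)/(N_{min}-1)$ when $g$ is the minimum sample size.
* **PLP** counts loci whose minority-state frequency in the rarefied
  sample *strictly* exceeds the level (default 5%); a single band in 20 at
  $g = 20$ is exactly 0.05 and is not counted. The threshold event has no
  convenient closed form under rarefaction, so PLP is a seeded Monte-Carlo
  mean over `plp_R` subsamples (default 1000); all other rarefied measures
  are exact.

Binomial coefficients are evaluated through `lchoose` differences, with
$\binom{a}{b} = 0$ for $a < b$, so the expectations are numerically stable
for any sample size.

**Cohort contrasts.** `ln_response_ratio()` computes per-population
$\ln(P_{SB}/P_{AG})$ and a two-sided 95% Student-t interval across
populations (df = populations − 1). The published analyses state the CI
criterion but not its construction; the t interval is the natural choice at
7–8 populations per habitat, and a seeded percentile bootstrap
(`method = "bootstrap"`) is provided as a sensitivity check. Zero metric
values are dropped with a warning rather than clamped, since a zero makes
the ratio undefined and typically reflects a rarefaction floor, not
biology.

## AMOVA and PCA

`pairwise_distance()` uses the squared Euclidean distance between band
phenotypes, i.e. the count of differing loci — the standard AMOVA metric
for binary data. Sums of squares follow the classical decomposition from
distance matrices; with unequal group sizes the variance components use the
usual $n_0$ coefficient (one-way) and the $n$, $n'$, $n''$ coefficients
(hierarchical), documented in the code. Negative variance components are
retained by default (a `truncate` flag clamps them), matching common
practice so that Φ values are comparable with published tables.

Permutation schemes follow the standard conventions per level: individuals
among groups for Φ\_ST, individuals among populations within regions for
Φ\_SC, and whole populations among regions for Φ\_CT. P-values use the
$(\text{hits}+1)/(n_{perm}+1)$ estimator, which cannot return zero. A
region containing a single population is flagged (`degenerate`) rather than
rejected: Φ\_CT is then computable but unstable.

`pca_scores()` centers but does not scale the binary matrix: unit-variance
scaling would upweight rare bands, which carry the least reliable signal in
AFLP data.

## Kinship for dominant markers and the Sp statistic

Spatial genetic structure is summarized from pairwise kinship
coefficients. For dominant markers the genotype is latent, so the
estimator needs an assumed inbreeding coefficient $F$ (default 0.5,
appropriate for a predominantly selfing perennial; the robustness check in
the test suite varies $F$ up to 0.9 and finds only modest shifts in Sp,
mirroring field experience).

Per locus, the null-allele frequency $q$ solves the band-absence
probability under inbreeding, $h = q^2(1-F) + qF$. For the phenotype
indicators $y_i, y_j$ of two individuals with kinship $\theta$, a
first-order identity-by-descent argument (condition on one cross-pair of
genes being IBD, probability $4\theta$ to first order; within-individual
genes are IBD with probability $F$) gives

$$\mathrm{Cov}(y_i, y_j) \approx 4\,p\,q\,(q + Fp)^2\,\theta,$$

with $p = 1 - q$. The moment estimator is therefore
$(y_i - f_\ell)(y_j - f_\ell)$ summed over loci, divided by the summed
per-locus coefficients $4pq(q+Fp)^2$ — a ratio-of-sums that weights each
locus by its information content. Reference frequencies $f_\ell$ come from
the analysed sample, so the pair-averaged kinship is centred near zero with
the usual $-O(1/n)$ bias of sample-referenced estimators. Loci with
band-absence frequency 0 or 1, or with an estimated $q$ outside $[0,1]$,
carry no information and are skipped with a warning. The test suite pins
the implementation to an independently coded scalar-loop version of the
same formulas at $10^{-10}$.

**Correlograms and Sp.** `correlogram()` averages kinship in half-open
distance classes (defaults 4, 8, 12, 16, 20 m); co-located pairs fall in
the first class. The null distribution permutes multilocus genotypes across
spatial positions (index permutation of the kinship matrix), giving
two-sided p-values and a 95% envelope per class. `sgs_summary()` regresses
pairwise kinship on ln(distance) over pairs with $0 < d \le 20$ m — the
pairwise (not class-mean) regression is the convention of the standard SGS
software; a `slope_on = "class_means"` alternative exists. Zero-distance
pairs enter $F(1)$ but not the log regression. Then

$$Sp = \frac{-b_{log}}{1 - F(1)}$$

measures the rate of kinship decay with distance: ~0.1+ is typical of
predominant selfers, ~0.01–0.04 of mixed maters.

**Seed-bank coordinates.** SB samples are germinated from trays pooling two
soil cells; `sb_coordinates()` places a sample at the midpoint of its
tray's source cells and excludes trays whose cells lie more than 4 m apart,
so the positional uncertainty stays within the first distance class.

**Heterogeneity tests.** `heterogeneity_test()` compares two correlograms:
per shared class the squared difference of class means standardized by its
permutation variance ($t^2_k$), and overall $\omega = \sum_k t^2_k$, with
significance conventionally declared at $p < 0.01$. The published method
names the implementing software but no formulas, so the standardization is
documented here as this package's interpretation: the null permutes
multilocus genotypes across positions *within each population block*, the
per-class variance is taken over the permuted differences, and p-values use
the $(\text{hits}+1)/(n_{perm}+1)$ estimator. Because permuting individuals
*between* groups would require kinship between cross-group pairs, the
function takes per-group marker matrices (not precomputed kinship) and
computes per-population kinship internally — with each population's own
reference frequencies, so that strong population divergence (Wahlund
effects) does not leak into within-population kinship. Only
within-population pairs enter the class means, which is what makes pooled
multi-population groups (e.g. "all meadow AG cohorts") well defined. A pair
bootstrap within group × class supplies confidence bars for plotting.

## The forward simulator

`simulate_metapopulation()` provides ground truth for every statistic. Per
generation and population: adults each produce a fixed number of seeds,
selfed with the habitat's probability, otherwise sired by a pollen donor
drawn with Gaussian kernel weights ($\sigma_p$); seeds disperse from the
mother by a Gaussian kernel ($\sigma_s$, re-drawn at the grid boundary, so
the kernel is truncated, not reflected); recruitment refills the carrying
capacity from the current seed rain plus the seed bank; unrecruited seeds
enter the bank and survive each year with fixed probability up to a maximum
age. Emitted markers are the dominant band phenotype of diploid diallelic
loci.

Defaults are the study conditions of the motivating survey: 15 populations
(regions R and T; 7 meadow, 8 woodland), 528 loci of which 24% segregate in
the founders, selfing 0.96 in meadows and 0.70 in woodlands (shade raises
outcrossing in partially cleistogamous violets), $\sigma_s = 1.3$ m,
$\sigma_p = 5$ m, no migration, and founder frequencies drawn from an
F-model with divergence 0.8 — reproducing the observed Φ\_ST ≈ 0.8 regime.
The seed-bank survival rate is not quantified in the field literature for
this system; 0.5/yr with maximum age 10 is a stated free parameter, not an
inference. Two modelling simplifications are deliberate: loci are diploid
although the species is octoploid (band phenotypes carry no dosage
information, and every statistic here is phenotype-based), and adult
generations are non-overlapping with a persistent seed pool (the tested
statistics do not depend on adult longevity).

`sample_aboveground()` and `sample_seed_bank()` emulate the field protocol:
19–23 adults from distinct occupied 1-m cells (with multi-sampling flagged
for stands smaller than the target), and 30 soil-sampled cells pooled
pairwise into 15 germination trays with 12–23 genotyped seedlings, at most
two per tray whenever the trays allow it. Tray provenance is recorded so
`sb_coordinates()` can apply the midpoint rule. Seedling emergence counts
are reported with densities per m² of soil surface (core diameter 5 cm);
`seedling_density()` also documents that the nominal 0.3 m² for 150 cores
slightly exceeds the exact core geometry (0.2945 m²).

What passing simulation tests show — and what they do not: the generator
reproduces the *statistical structure* the analysis assumes (binary
phenotypes from drifted allele frequencies, selfing-driven identity,
spatially local dispersal, geometric bank ages). It does not emulate
scoring noise, size homoplasy, polyploid dosage, flowering phenology or
selection, so agreement on simulated data validates the estimators, not the
field protocol.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains filter → diversity → LnRR → AMOVA (one-way,
hierarchical, pairwise, AG-vs-SB) → PCA → per-population SGS → pooled
heterogeneity comparisons, writing every table with a config fingerprint
and the master seed; all stage streams derive from that one seed, so reruns
are byte-identical. Stage failures (a missing cohort, a region with one
population) are logged and skipped rather than fatal.

Defaults follow the motivating survey throughout (g = 12, F = 0.5, classes
4–20 m, 9999 permutations and bootstraps, heterogeneity α = 0.01). The
test suite and the bundled acceptance checks run the same machinery at
reduced problem sizes chosen to keep the full suite around a minute on one
CPU — e.g. 6 of 15 populations, 120–300 loci, 49–199 permutations, and
Monte-Carlo oracles at 3000–10000 draws; these sizes are statistical
choices (3-standard-error bands for the oracles, sign tests over 10 paired
replicates for parameter recovery) and are stated in the tests themselves.

## Known limitations

* The kinship coefficient is a first-order moment estimator; for pairs of
  highly inbred close relatives its linearity in $\theta$ underestimates
  the covariance, as for all estimators of this family.
* PLP is Monte-Carlo; its reproducibility is per-seed, and its standard
  error scales as $R^{-1/2}$.
* The heterogeneity test's standardization is this package's documented
  interpretation of a method whose reference implementation is closed
  binary-only software; absolute ω values may differ from that software
  even when decisions agree.
* Permutation p-values depend on the RNG stream: they are reproducible
  under a fixed seed but not invariant to reordering the input rows.
* No isolation-by-distance (Mantel) machinery and no allele-frequency
  diversity (He, F\_IS): both are outside the band-based scope.
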