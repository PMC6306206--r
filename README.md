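# aflpop

Band-based population genetics for dominant markers, built around the
comparison of **aboveground (AG)** and **soil seed-bank (SB)** cohorts of
plant populations scored with AFLP (binary band-phenotype) data.

Dominant markers hide the heterozygote, so `aflpop` works throughout on the
0/1 band phenotype and never on allele frequencies — except where a model of
inbreeding makes the allele frequency identifiable. The package covers the
full analysis chain used in seed-bank population genetics:

- **Locus QC**: removal of monomorphic and single-deviant loci, and a
  replicate-based genotyping error rate.
- **Rarefied diversity** at a standardized sample size *g*: band richness
  *Br* (expected band states per locus, in [1, 2]), percentage of
  polymorphic loci *PLP* at the 5% level, Kalinowski-style private band
  richness *PBr* between paired cohorts, and the rarefied number of
  multilocus phenotypes *eMLG* with *P*<sub>u</sub> = (eMLG − 1)/(g − 1).
- **Cohort contrasts** as natural-log response ratios,
  LnRR = ln(*P*<sub>SB</sub>/*P*<sub>AG</sub>), with per-habitat Student-t
  confidence intervals across populations.
- **AMOVA** (one-way and region/population hierarchical) from squared
  band-phenotype distances, with Φ<sub>ST</sub>, Φ<sub>SC</sub>,
  Φ<sub>CT</sub> and permutation tests; pairwise Φ<sub>ST</sub> matrices;
  PCA of the centered binary matrix.
- **Small-scale spatial genetic structure (SGS)**: pairwise kinship
  *F*<sub>ij</sub> for dominant markers under an assumed inbreeding
  coefficient *F* (default 0.5), distance-class correlograms with
  permutation envelopes, the restricted (0–20 m) regression slope
  *b*<sub>log</sub> of kinship on ln(distance), and
  **Sp = −*b*<sub>log</sub>/(1 − *F*(1))**, plus per-class *t*² and overall
  ω heterogeneity tests between correlograms.
- A **forward-time simulator** of partially selfing, seed-banking plant
  populations on a 1-m grid (Gaussian pollen/seed dispersal, geometric
  seed-bank survival, no migration) with field-sampling emulators for both
  cohorts, so every statistic can be validated against known ground truth.

The defaults mirror a 15-population, two-region × two-habitat *Viola
elatior* survey (~96% selfing in meadows, Φ<sub>ST</sub> ≈ 0.8, rarefaction
size 12, distance classes 4–20 m, 9999 permutations); its published
per-population summary tables ship with the package
(`viola_reference_sgs()`, `viola_reference_diversity()`).

## Worked example

Recompute the Sp statistic from the published kinship-regression
ingredients of population RM4 (aboveground cohort):

```r
library(aflpop)
sgs <- viola_reference_sgs()
rm4 <- sgs[sgs$population == "RM4", ]
sp_statistic(F1 = rm4$F1_ag, b_log = rm4$b_log_ag)
#> [1] 0.7027915
```

With *F*(1) = 0.391 and *b*<sub>log</sub> = −0.428 this gives 0.703: kinship
among plants within 4 m is high and falls steeply with log distance — the
signature of a highly selfing population with seed dispersal of ~1 m.

Run the whole pipeline on a simulated six-population survey (two habitats,
both regions; permutation counts reduced for a quick look):

```r
layout <- default_population_layout()[c(1, 2, 5, 8, 11, 12), ]
sim <- simulation_config(populations = layout, n_loci = 200,
                         capacity = c(meadow = 80, woodland = 50),
                         n_generations = 15, seed = 1)
bundle <- run_pipeline(pipeline_config(sim_config = sim, n_perm = 199,
                                       n_boot = 99, seed = 1))
subset(bundle$amova, model == "one-way" & cohort == "AG")
#>   cohort   model        source  df       SS    sigma pct_total     p       phi
#> 1     AG one-way  Among groups   5 757.0523 6.904009  78.40555 0.005 0.7840555
#> 2     AG one-way Within groups 124 235.7861 1.901501  21.59445    NA        NA

head(bundle$sgs, 4)
#>   population cohort  n          F1       b_log         Sp p_F1 p_b_log
#> 1        RM1     AG 23  0.05136937 -0.05761000 0.06072965 0.01    0.01
#> 2        RM1     SB 17  0.00295483 -0.03138153 0.03147453 0.18    0.05
#> 3        RM2     AG 22  0.03895627 -0.06785710 0.07060771 0.12    0.01
#> 4        RM2     SB 10 -0.02331420 -0.03074216 0.03004176 0.83    0.27
```

78% of molecular variance lies among populations (Φ<sub>ST</sub> = 0.78,
p = 0.005) — strong drift under high selfing and no migration — and the
meadow aboveground cohorts show significant small-scale structure
(p(*b*<sub>log</sub>) = 0.01). With `out_dir` set, every table is written
as CSV stamped with a config fingerprint and the seed; reruns with the same
seed are byte-identical.

A thin command-line wrapper lives at `inst/scripts/aflpop-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/aflpop-pipeline.R", package="aflpop"))')" \
  --habitat meadow --n-perm 999 --seed 1 --out-dir report
```

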