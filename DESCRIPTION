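Package: aflpop
Title: Dominant-Marker Population Genetics for Aboveground and Seed-Bank Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band-based (dominant AFLP phenotype) population-genetic analysis
    of paired aboveground and soil seed-bank cohorts: rarefaction diversity
    (band richness, polymorphic-locus percentage, private band richness,
    expected multilocus genotypes), log response ratios with confidence
    intervals, one-way and hierarchical AMOVA with permutation tests and
    pairwise phi-ST, principal component analysis, dominant-marker kinship
    coefficients under an assumed inbreeding coefficient, distance-class
    correlograms, the Sp statistic of small-scale spatial genetic structure,
    and correlogram heterogeneity tests.  Includes a forward-time simulator
    of partially selfing, seed-banking plant populations on a spatial grid
    together with field-sampling emulators, so that every statistic can be
    exercised against data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
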