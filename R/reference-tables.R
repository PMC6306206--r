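#' Published per-population summary statistics of the motivating survey
#'
#' The field survey that motivates this package's defaults — 15 *Viola
#' elatior* populations in two regions and two habitats, with paired
#' aboveground (AG) and seed-bank (SB) cohorts scored at 528 AFLP loci —
#' deposited no raw genotypes, but its per-population summary statistics
#' are public.  These accessors return them as data frames for worked
#' examples and for arithmetic checks of the package's statistics
#' (e.g. recomputing Sp from its printed regression ingredients with
#' [sp_statistic()]).
#'
#' `viola_reference_sgs()`: per population, cohort sample sizes and the
#' small-scale spatial genetic structure ingredients `F1` (mean kinship of
#' the first distance class), `b_log` (kinship-on-ln-distance slope over
#' 0-20 m) and the published `Sp`, per cohort.
#'
#' `viola_reference_diversity()`: per population, rarefied (g = 12) band
#' richness `br`, percentage of polymorphic loci `plp`, private band
#' richness `pbr` and proportion of unique phenotypes `pu`, per cohort.
#'
#' @return a data.frame keyed by `population` with `region` and `habitat`
#'   columns; metric columns carry `_ag`/`_sb` suffixes.
#' @examples
#' sgs <- viola_reference_sgs()
#' sp_statistic(F1 = sgs$F1_ag, b_log = sgs$b_log_ag)
#' @export
viola_reference_sgs <- function() {
  utils::read.csv(system.file("extdata", "viola_elatior_sgs.csv",
                              package = "aflpop"),
                  stringsAsFactors = FALSE)
}

#' @rdname viola_reference_sgs
#' @export
viola_reference_diversity <- function() {
  utils::read.csv(system.file("extdata", "viola_elatior_diversity.csv",
                              package = "aflpop"),
                  stringsAsFactors = FALSE)
}
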