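#' Per-population, per-cohort rarefied diversity table
#'
#' Computes band richness (Br), percentage of polymorphic loci (PLP),
#' private band richness versus the paired cohort (PBr) and the rarefied
#' proportion of unique multilocus phenotypes (Pu, with its eMLG) for every
#' (population, cohort) group, all at a common rarefaction size `g`.
#' Groups smaller than `g` are flagged and skipped; populations lacking one
#' cohort get an empty PBr with a warning.
#'
#' @param m a [marker_matrix()] (typically post [filter_loci()]).
#' @param s a [sample_table()] covering all rows of `m`.
#' @param g rarefaction size; the conventional choice is the smallest group
#'   size (12 in the motivating 15-population survey).
#' @param plp_level minority-frequency level for PLP.
#' @param plp_R,seed Monte-Carlo settings passed to [plp()].
#' @return data.frame of class `rarefied_diversity_table` with one row per
#'   (population, cohort): columns `population, habitat, region, cohort, N,
#'   g, Br, PLP, PBr, eMLG, Pu, skipped`.
#' @export
diversity_table <- function(m, s, g = 12L, plp_level = 0.05,
                            plp_R = 1000L, seed = 1L) {
  s <- align_samples(m, s)
  groups <- split(s$sample_id, list(s$population, s$cohort), drop = TRUE)
  pops <- sort(unique(s$population))
  rows <- list()
  for (pop in pops) {
    pop_meta <- s[s$population == pop, ][1L, ]
    for (cohort in c("AG", "SB")) {
      ids <- s$sample_id[s$population == pop & s$cohort == cohort]
      if (!length(ids)) next
      N <- length(ids)
      row <- data.frame(population = pop, habitat = pop_meta$habitat,
                        region = pop_meta$region, cohort = cohort,
                        N = N, g = g, Br = NA_real_, PLP = NA_real_,
                        PBr = NA_real_, eMLG = NA_real_, Pu = NA_real_,
                        skipped = FALSE, stringsAsFactors = FALSE)
      if (N < g) {
        warning(sprintf("%s/%s has N = %d < g = %d; skipped",
                        pop, cohort, N, g), call. = FALSE)
        row$skipped <- TRUE
        rows[[length(rows) + 1L]] <- row
        next
      }
      sub <- subset_samples(m, ids)
      row$Br <- band_richness(sub, g)$Br
      row$PLP <- plp(sub, g, level = plp_level, R = plp_R,
                     seed = derive_seed(seed, match(pop, pops)))
      pu <- proportion_unique(sub, g)
      row$eMLG <- pu[["eMLG"]]
      row$Pu <- pu[["Pu"]]
      other <- s$sample_id[s$population == pop & s$cohort != cohort]
      if (length(other) >= g) {
        pb <- private_band_richness(sub, subset_samples(m, other), g)
        row$PBr <- pb[["PBr_a"]]
      } else {
        warning(sprintf("%s/%s: paired cohort absent or smaller than g; PBr empty",
                        pop, cohort), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rarefied_diversity_table", "data.frame")
  out
}

#' Log response ratio of seed-bank versus aboveground diversity
#'
#' For each population with both cohorts, computes
#' `lnRR_p = ln(SB_p / AG_p)` for the chosen metric and summarizes across
#' populations with a mean and two-sided 95% Student-t confidence interval
#' (df = number of populations - 1).  The difference is declared
#' significant when the interval excludes zero.  A seeded percentile
#' bootstrap interval is available as an alternative.
#'
#' @param table a [diversity_table()] result.
#' @param metric one of `"Br"`, `"PLP"`, `"PBr"`, `"Pu"`.
#' @param habitat optional habitat filter (`"meadow"` or `"woodland"`);
#'   `NULL` pools all populations.
#' @param conf confidence level.
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param boot_R,seed bootstrap settings.
#' @return list of class `response_ratio`: `metric, habitat, mean_lnrr,
#'   ci_low, ci_high, n_pops, significant, per_population`.
#' @export
ln_response_ratio <- function(table, metric = c("Br", "PLP", "PBr", "Pu"),
                              habitat = NULL, conf = 0.95,
                              method = c("t", "bootstrap"),
                              boot_R = 10000L, seed = 1L) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  tab <- as.data.frame(table)
  tab <- tab[!tab$skipped, ]
  if (!is.null(habitat)) tab <- tab[tab$habitat == habitat, ]
  wide <- merge(tab[tab$cohort == "AG", c("population", metric)],
                tab[tab$cohort == "SB", c("population", metric)],
                by = "population", suffixes = c("_AG", "_SB"))
  ag <- wide[[paste0(metric, "_AG")]]
  sb <- wide[[paste0(metric, "_SB")]]
  usable <- is.finite(ag) & is.finite(sb) & ag > 0 & sb > 0
  if (any(!usable)) {
    warning(sprintf("%d population(s) dropped (zero or missing %s values)",
                    sum(!usable), metric), call. = FALSE)
  }
  lnrr <- log(sb[usable] / ag[usable])
  n <- length(lnrr)
  if (n < 2L) {
    stop("fewer than 2 usable populations for the response ratio", call. = FALSE)
  }
  mean_lnrr <- mean(lnrr)
  if (method == "t") {
    se <- stats::sd(lnrr) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
    ci <- mean_lnrr + c(-1, 1) * tq * se
  } else {
    boots <- with_seed(seed, vapply(seq_len(boot_R), function(b) {
      mean(lnrr[sample.int(n, n, replace = TRUE)])
    }, numeric(1)))
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(metric = metric,
                 habitat = if (is.null(habitat)) "all" else habitat,
                 mean_lnrr = mean_lnrr, ci_low = ci[1L], ci_high = ci[2L],
                 n_pops = n, significant = ci[1L] > 0 || ci[2L] < 0,
                 per_population = data.frame(population = wide$population[usable],
                                             lnrr = lnrr)),
            class = "response_ratio")
}

#' @export
print.response_ratio <- function(x, ...) {
  cat(sprintf("<response_ratio> %s (%s): mean LnRR %.3f [%.3f, %.3f], n = %d%s\n",
              x$metric, x$habitat, x$mean_lnrr, x$ci_low, x$ci_high, x$n_pops,
              if (x$significant) " *" else ""))
  invisible(x)
}
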