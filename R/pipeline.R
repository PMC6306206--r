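#' Seedling density per square metre of soil surface
#'
#' @param count number of emerged seedlings.
#' @param area_m2 sampled soil surface (m^2); must be positive.  The
#'   conventional nominal value for 150 cores of 5 cm diameter is 0.3 m^2
#'   (the recomputed core geometry gives 150 * pi * 0.025^2 = 0.2945 m^2).
#' @return seedlings per m^2.
#' @examples
#' seedling_density(12, 0.3)  # 40
#' @export
seedling_density <- function(count, area_m2) {
  if (area_m2 <= 0) stop("area must be positive", call. = FALSE)
  count / area_m2
}

#' Pipeline configuration
#'
#' Defaults equal the conventional settings of the motivating survey:
#' rarefaction size 12, inbreeding coefficient 0.5, distance classes
#' 4/8/12/16/20 m, 9999 permutations and bootstraps, heterogeneity alpha
#' 0.01.  All are overridable.
#'
#' @param marker_path,sample_path input CSV/TSV paths; when `NULL` the
#'   pipeline simulates a dataset from `sim_config`.
#' @param sim_config a [simulation_config()] (default: the full
#'   15-population layout).
#' @param g rarefaction size.
#' @param inbreeding_f assumed inbreeding coefficient for kinship.
#' @param class_limits distance class upper bounds (m).
#' @param n_perm,n_boot permutation/bootstrap counts.
#' @param het_alpha significance level of the heterogeneity tests.
#' @param plp_R Monte-Carlo subsamples for PLP.
#' @param seed master RNG seed; every stage derives its stream from it.
#' @param out_dir output directory for report CSVs (`NULL` = no files).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(marker_path = NULL, sample_path = NULL,
                            sim_config = NULL, g = 12L, inbreeding_f = 0.5,
                            class_limits = c(4, 8, 12, 16, 20),
                            n_perm = 9999L, n_boot = 9999L, het_alpha = 0.01,
                            plp_R = 1000L, seed = 1L, out_dir = NULL) {
  if (is.null(marker_path) && is.null(sim_config)) {
    sim_config <- simulation_config(seed = derive_seed(seed, 99L))
  }
  structure(list(marker_path = marker_path, sample_path = sample_path,
                 sim_config = sim_config, g = as.integer(g),
                 inbreeding_f = inbreeding_f, class_limits = class_limits,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 het_alpha = het_alpha, plp_R = as.integer(plp_R),
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

# order-insensitive-enough content hash of the analysis parameters (FNV-1a
# over the deparsed config, arithmetic kept below 2^53)
config_fingerprint <- function(cfg) {
  keys <- cfg[setdiff(names(cfg), c("marker_path", "sample_path", "out_dir"))]
  txt <- paste(deparse(keys), collapse = "")
  h <- 5381
  for (v in utf8ToInt(txt)) {
    h <- (h * 33 + v) %% 2^31
  }
  sprintf("%08x", h)
}

write_report_csv <- function(df, path, fingerprint, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# aflpop config %s seed %s", fingerprint, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full two-cohort analysis pipeline
#'
#' Orchestrates locus filtering, rarefied diversity and log response
#' ratios, one-way and hierarchical AMOVA per cohort, pairwise phi-ST
#' (population pairs per cohort and AG-vs-SB within populations), PCA,
#' per-population small-scale spatial genetic structure, and pooled
#' correlogram heterogeneity comparisons (meadow vs woodland aboveground,
#' AG vs SB within each habitat, and per-region habitat contrasts).
#' Stage failures are logged with the stage name and downstream stages
#' skip gracefully.  With the same configuration and inputs the report is
#' reproduced bit-exactly.
#'
#' @param cfg a [pipeline_config()].
#' @return a `report_bundle` list of tables (`diversity`, `diversity_means`,
#'   `lnrr`, `amova`, `pairwise_phi`, `cohort_phi`, `pca`, `sgs`,
#'   `heterogeneity`, `qc`, `log`, `fingerprint`).  When `cfg$out_dir` is
#'   set, each table is also written as CSV with a config/seed header line.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fp <- config_fingerprint(cfg)
  bundle <- list(fingerprint = fp, seed = cfg$seed, log = character(0))
  note <- function(...) {
    bundle$log <<- c(bundle$log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("ERROR [%s]: %s", name, conditionMessage(e))
      NULL
    })
  }

  # --- inputs ------------------------------------------------------------
  sim <- NULL
  if (!is.null(cfg$marker_path)) {
    markers <- read_marker_matrix(cfg$marker_path)
    samples <- read_sample_table(cfg$sample_path)
    note("inputs: read %d samples x %d loci", nrow(markers), ncol(markers))
  } else {
    sim <- simulate_survey(cfg$sim_config, seed = derive_seed(cfg$seed, 1L))
    markers <- sim$markers
    samples <- sim$samples
    note("inputs: simulated %d samples x %d loci (fingerprint %s)",
         nrow(markers), ncol(markers), fp)
  }
  samples <- align_samples(markers, samples)

  # --- locus filter ------------------------------------------------------
  filt <- filter_loci(markers)
  m <- filt$matrix
  note("filter: retained %d of %d loci", filt$report$n_retained,
       filt$report$n_input_loci)

  # --- diversity ---------------------------------------------------------
  bundle$diversity <- stage("diversity", {
    withCallingHandlers(
      diversity_table(m, samples, g = cfg$g, plp_R = cfg$plp_R,
                      seed = derive_seed(cfg$seed, 2L)),
      warning = function(w) {
        note("diversity: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  if (!is.null(bundle$diversity)) {
    tab <- as.data.frame(bundle$diversity)
    ok <- !tab$skipped
    agg <- stats::aggregate(tab[ok, c("Br", "PLP", "PBr", "Pu")],
                            by = list(cohort = tab$cohort[ok]), FUN = mean,
                            na.rm = TRUE)
    agg_h <- stats::aggregate(tab[ok, c("Br", "PLP", "PBr", "Pu")],
                              by = list(cohort = tab$cohort[ok],
                                        habitat = tab$habitat[ok]),
                              FUN = mean, na.rm = TRUE)
    agg$habitat <- "all"
    bundle$diversity_means <- rbind(agg[names(agg_h)], agg_h)
  }
  bundle$lnrr <- stage("lnrr", {
    rows <- list()
    for (hab in unique(samples$habitat)) {
      for (met in c("Br", "PLP", "PBr", "Pu")) {
        rr <- tryCatch(suppressWarnings(
          ln_response_ratio(bundle$diversity, metric = met, habitat = hab)),
          error = function(e) NULL)
        if (is.null(rr)) { note("lnrr: skipped %s/%s", hab, met); next }
        rows[[paste(hab, met)]] <- data.frame(
          habitat = hab, metric = met, mean_lnrr = rr$mean_lnrr,
          ci_low = rr$ci_low, ci_high = rr$ci_high, n_pops = rr$n_pops,
          significant = rr$significant)
      }
    }
    rbind_rows(rows)
  })

  # --- AMOVA / PCA -------------------------------------------------------
  bundle$amova <- stage("amova", {
    rows <- list()
    for (coh in c("AG", "SB")) {
      ids <- samples$sample_id[samples$cohort == coh]
      sub <- subset_samples(m, ids)
      meta <- samples[match(ids, samples$sample_id), ]
      d <- pairwise_distance(sub)
      one <- tryCatch(
        amova_oneway(d, meta$population, n_perm = cfg$n_perm,
                     seed = derive_seed(cfg$seed, 3L)),
        error = function(e) {
          note("amova: one-way skipped for %s (%s)", coh,
               conditionMessage(e))
          NULL
        })
      if (is.null(one)) next
      rows[[coh]] <- data.frame(cohort = coh, model = "one-way", one$levels,
                                phi = c(one$phi_st, NA))
      hier <- tryCatch(suppressWarnings(
        amova_hierarchical(d, meta$region, meta$population,
                           n_perm = cfg$n_perm,
                           seed = derive_seed(cfg$seed, 4L))),
        error = function(e) {
          note("amova: hierarchical skipped for %s (%s)", coh,
               conditionMessage(e))
          NULL
        })
      if (!is.null(hier)) {
        rows[[paste0(coh, "_hier")]] <- data.frame(
          cohort = coh, model = "hierarchical", hier$levels,
          phi = c(hier$phi_ct, hier$phi_sc, hier$phi_st))
      }
    }
    rbind_rows(rows)
  })
  bundle$pairwise_phi <- stage("pairwise_phi", {
    rows <- list()
    for (coh in c("AG", "SB")) {
      ids <- samples$sample_id[samples$cohort == coh]
      pw <- suppressWarnings(
        pairwise_phi_st(subset_samples(m, ids),
                        samples[match(ids, samples$sample_id), ],
                        pairing = "population", n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, 5L)))
      rows[[coh]] <- data.frame(cohort = coh, as.data.frame(pw))
    }
    rbind_rows(rows)
  })
  bundle$cohort_phi <- stage("cohort_phi", {
    withCallingHandlers(
      pairwise_phi_st(m, samples, pairing = "cohort", n_perm = cfg$n_perm,
                      seed = derive_seed(cfg$seed, 6L)),
      warning = function(w) {
        note("cohort_phi: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  bundle$pca <- stage("pca", {
    pc <- pca_scores(m)
    k <- min(3L, pc$n_components)
    data.frame(component = seq_len(k),
               variance_fraction = pc$variance_fraction[seq_len(k)],
               pct = 100 * pc$variance_fraction[seq_len(k)])
  })

  # --- small-scale spatial genetic structure -----------------------------
  coords_all <- stage("sb_coordinates", {
    suppressWarnings(sb_coordinates(samples))
  })
  bundle$sgs <- stage("sgs", {
    rows <- list()
    for (pop in unique(samples$population)) {
      for (coh in c("AG", "SB")) {
        sel <- samples$population == pop & samples$cohort == coh
        ids <- samples$sample_id[sel]
        if (length(ids) < 4L) next
        co <- coords_all[match(ids, coords_all$sample_id), ]
        res <- tryCatch(suppressWarnings({
          kin <- kinship_matrix(subset_samples(m, ids), cfg$inbreeding_f)
          sgs_summary(kin, co, max_dist = max(cfg$class_limits),
                      first_class_limit = cfg$class_limits[1L],
                      n_perm = cfg$n_perm,
                      seed = derive_seed(cfg$seed, 7L),
                      class_limits = cfg$class_limits)
        }), error = function(e) {
          note("sgs: skipped %s/%s (%s)", pop, coh, conditionMessage(e))
          NULL
        })
        if (is.null(res)) next
        rows[[paste(pop, coh)]] <- data.frame(
          population = pop, cohort = coh, n = res$n, F1 = res$F1,
          b_log = res$b_log, Sp = res$Sp, p_F1 = res$p_F1,
          p_b_log = res$p_b_log)
      }
    }
    rbind_rows(rows)
  })

  # --- pooled heterogeneity comparisons ----------------------------------
  bundle$heterogeneity <- stage("heterogeneity", {
    grp <- function(sel) {
      ids <- samples$sample_id[sel]
      co <- coords_all[match(ids, coords_all$sample_id), ]
      list(markers = subset_samples(m, ids), coords = co,
           populations = samples$population[sel])
    }
    comparisons <- list(
      AG_meadow_vs_woodland = list(
        a = samples$cohort == "AG" & samples$habitat == "meadow",
        b = samples$cohort == "AG" & samples$habitat == "woodland"),
      meadow_AG_vs_SB = list(
        a = samples$cohort == "AG" & samples$habitat == "meadow",
        b = samples$cohort == "SB" & samples$habitat == "meadow"),
      woodland_AG_vs_SB = list(
        a = samples$cohort == "AG" & samples$habitat == "woodland",
        b = samples$cohort == "SB" & samples$habitat == "woodland"))
    for (reg in unique(samples$region)) {
      comparisons[[sprintf("AG_meadow_vs_woodland_region_%s", reg)]] <- list(
        a = samples$cohort == "AG" & samples$habitat == "meadow" &
          samples$region == reg,
        b = samples$cohort == "AG" & samples$habitat == "woodland" &
          samples$region == reg)
    }
    rows <- list()
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      if (!any(cmp$a) || !any(cmp$b)) {
        note("heterogeneity: skipped %s (empty group)", nm)
        next
      }
      res <- tryCatch(suppressWarnings(
        heterogeneity_test(grp(cmp$a), grp(cmp$b),
                           class_limits = cfg$class_limits,
                           n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                           seed = derive_seed(cfg$seed, 8L),
                           inbreeding_f = cfg$inbreeding_f,
                           alpha = cfg$het_alpha)),
        error = function(e) {
          note("heterogeneity: skipped %s (%s)", nm, conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      rows[[nm]] <- data.frame(comparison = nm, omega = res$omega,
                               p = res$p_omega,
                               significant = res$significant)
    }
    rbind_rows(rows)
  })

  # --- QC ----------------------------------------------------------------
  bundle$qc <- stage("qc", {
    qc <- data.frame(
      key = c("n_input_loci", "n_monomorphic", "n_single_deviant",
              "n_retained", "pct_polymorphic"),
      value = c(filt$report$n_input_loci, filt$report$n_monomorphic,
                filt$report$n_single_deviant, filt$report$n_retained,
                100 * filt$report$n_retained / filt$report$n_input_loci))
    if (!is.null(sim)) {
      qc <- rbind(qc, data.frame(
        key = paste0("seedlings_per_m2_", sim$seedling_counts$population),
        value = sim$seedling_counts$seedlings_per_m2))
    }
    qc
  })

  # --- write -------------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("diversity", "diversity_means", "lnrr", "amova",
                "pairwise_phi", "cohort_phi", "pca", "sgs", "heterogeneity",
                "qc")
    for (nm in tables) {
      if (!is.null(bundle[[nm]])) {
        write_report_csv(as.data.frame(bundle[[nm]]),
                         file.path(cfg$out_dir, paste0(nm, ".csv")),
                         fp, cfg$seed)
      }
    }
    writeLines(bundle$log, file.path(cfg$out_dir, "pipeline.log"))
  }
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> fingerprint %s, seed %s\n", x$fingerprint,
              x$seed))
  for (nm in setdiff(names(x), c("fingerprint", "seed", "log"))) {
    obj <- x[[nm]]
    if (is.data.frame(obj)) cat(sprintf("  %s: %d rows\n", nm, nrow(obj)))
  }
  if (length(x$log)) cat(sprintf("  log: %d entries\n", length(x$log)))
  invisible(x)
}
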