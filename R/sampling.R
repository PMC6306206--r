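#' Emulate aboveground field sampling on the 1-m grid
#'
#' Draws a per-population target of 19-23 occupied 1-m grid cells (uniform
#' within the range) and samples one adult per selected cell, recording the
#' cell coordinates.  When a population occupies fewer cells than the
#' target, all its cells are used and extra individuals are drawn from
#' already-sampled cells, with the population flagged as multi-sampled
#' (mirroring small stands where the mapped cells do not cover the target).
#'
#' @param ds a `sim_dataset` from [simulate_metapopulation()].
#' @param n_range integer range of per-population sample sizes.
#' @param seed RNG seed.
#' @return list with `markers` ([marker_matrix()] of band phenotypes),
#'   `samples` ([sample_table()] with cohort `"AG"`), and a `flags`
#'   data.frame (`population`, `n_cells`, `multi_sampled`).
#' @export
sample_aboveground <- function(ds, n_range = c(19L, 23L), seed = 1L) {
  stopifnot(inherits(ds, "sim_dataset"))
  layout <- ds$cfg$populations
  with_seed(seed, {
    mats <- list(); metas <- list(); flags <- list()
    for (i in seq_len(nrow(layout))) {
      pop <- layout$population[i]
      ad <- ds$populations[[pop]]$adults
      n_ad <- nrow(ad$a1)
      if (!n_ad) stop(sprintf("population %s has no adults", pop), call. = FALSE)
      cell <- paste(floor(ad$x), floor(ad$y))
      cells <- unique(cell)
      target <- sample(seq.int(n_range[1L], n_range[2L]), 1L)
      multi <- length(cells) < target
      if (!multi) {
        chosen_cells <- sample(cells, target)
        idx <- vapply(chosen_cells, function(cc) {
          occ <- which(cell == cc)
          if (length(occ) == 1L) occ else sample(occ, 1L)
        }, integer(1))
      } else {
        idx <- vapply(cells, function(cc) {
          occ <- which(cell == cc)
          if (length(occ) == 1L) occ else sample(occ, 1L)
        }, integer(1))
        extra_n <- min(target, n_ad) - length(idx)
        if (extra_n > 0L) {
          remaining <- setdiff(seq_len(n_ad), idx)
          idx <- c(idx, sample_safe(remaining, min(extra_n, length(remaining))))
        }
      }
      ids <- sprintf("%s_AG_%02d", pop, seq_along(idx))
      mats[[pop]] <- band_phenotype(ad$a1[idx, , drop = FALSE],
                                    ad$a2[idx, , drop = FALSE])
      rownames(mats[[pop]]) <- ids
      metas[[pop]] <- data.frame(
        sample_id = ids, population = pop, region = layout$region[i],
        habitat = layout$habitat[i], cohort = "AG",
        x = floor(ad$x[idx]), y = floor(ad$y[idx]),
        tray_id = NA_character_, stringsAsFactors = FALSE)
      flags[[pop]] <- data.frame(population = pop, n_cells = length(cells),
                                 multi_sampled = multi)
    }
    values <- do.call(rbind, mats)
    colnames(values) <- sprintf("L%03d", seq_len(ncol(values)))
    list(markers = marker_matrix(values),
         samples = sample_table(do.call(rbind, metas)),
         flags = do.call(rbind, flags))
  })
}

# greedy nearest-neighbour pairing of cells into trays
pair_cells <- function(cx, cy) {
  n <- length(cx)
  unpaired <- seq_len(n)
  pairs <- list()
  while (length(unpaired) >= 2L) {
    a <- unpaired[1L]
    rest <- unpaired[-1L]
    dd <- (cx[rest] - cx[a])^2 + (cy[rest] - cy[a])^2
    b <- rest[which.min(dd)]
    pairs[[length(pairs) + 1L]] <- c(a, b)
    unpaired <- setdiff(unpaired, c(a, b))
  }
  if (length(unpaired) == 1L) {
    # odd cell count: last tray holds a single cell (both slots identical)
    pairs[[length(pairs) + 1L]] <- c(unpaired, unpaired)
  }
  do.call(rbind, pairs)
}

#' Emulate seed-bank sampling via the seedling-emergence method
#'
#' Per population: soil is taken from up to `n_cells` randomly selected
#' occupied grid cells (`cores_per_cell` cores each, pooling the cell's
#' germinable seed content); proximate cell pairs are pooled into
#' germination trays; banked seeds resting in the chosen cells germinate
#' independently with probability `germination`; a per-population target of
#' 12-23 genotyped samples is then drawn, taking whenever possible only one
#' to two seedlings per tray.  Each SB sample records its tray and the
#' tray's two source-cell coordinates for [sb_coordinates()]; its working
#' coordinates are the tray midpoint.
#'
#' @param ds a `sim_dataset`.
#' @param n_cells soil-sampled grid cells per population.
#' @param cores_per_cell soil cores per cell (bookkeeping for the reported
#'   sampled area).
#' @param germination per-seed germination probability in the trays.
#' @param n_range integer range of genotyped SB samples per population.
#' @param seed RNG seed.
#' @return list with `markers`, `samples` (cohort `"SB"`, with `tray_id`
#'   and tray source-cell columns) and `seedling_counts` per population
#'   (emerged seedlings and seedlings per square metre of soil surface,
#'   core diameter 5 cm).
#' @export
sample_seed_bank <- function(ds, n_cells = 30L, cores_per_cell = 5L,
                             germination = 0.5, n_range = c(12L, 23L),
                             seed = 1L) {
  stopifnot(inherits(ds, "sim_dataset"))
  layout <- ds$cfg$populations
  core_diameter <- 0.05  # m, per soil core
  with_seed(seed, {
    mats <- list(); metas <- list(); counts <- list()
    for (i in seq_len(nrow(layout))) {
      pop <- layout$population[i]
      bank <- ds$populations[[pop]]$bank
      ad <- ds$populations[[pop]]$adults
      occupied <- unique(cbind(floor(ad$x), floor(ad$y)))
      take <- min(n_cells, nrow(occupied))
      chosen <- occupied[sample.int(nrow(occupied), take), , drop = FALSE]
      trays <- pair_cells(chosen[, 1L], chosen[, 2L])
      if (!length(bank$age)) {
        stop(sprintf("population %s has an empty seed bank", pop), call. = FALSE)
      }
      seed_cell <- cbind(floor(bank$x), floor(bank$y))
      tray_of_seed <- rep(NA_integer_, length(bank$age))
      for (tr in seq_len(nrow(trays))) {
        for (slot in unique(trays[tr, ])) {
          hit <- which(seed_cell[, 1L] == chosen[slot, 1L] &
                         seed_cell[, 2L] == chosen[slot, 2L])
          tray_of_seed[hit] <- tr
        }
      }
      captured <- which(!is.na(tray_of_seed))
      germ <- captured[stats::runif(length(captured)) < germination]
      if (!length(germ)) {
        stop(sprintf("population %s: no germinable seeds in the sampled cells",
                     pop), call. = FALSE)
      }
      target <- sample(seq.int(n_range[1L], n_range[2L]), 1L)
      sel <- integer(0)
      germ_trays <- unique(tray_of_seed[germ])
      for (cap in 1:2) {  # first one per tray, then a second where needed
        tray_order <- if (length(germ_trays) > 1L) sample(germ_trays) else germ_trays
        for (tr in tray_order) {
          if (length(sel) >= target) break
          in_tray <- setdiff(germ[tray_of_seed[germ] == tr], sel)
          already <- sum(tray_of_seed[sel] == tr)
          if (length(in_tray) && already < cap) {
            sel <- c(sel, sample_safe(in_tray, 1L))
          }
        }
        if (length(sel) >= target) break
      }
      if (length(sel) < target) {  # per-tray cap relaxed only when unavoidable
        remaining <- setdiff(germ, sel)
        sel <- c(sel, sample_safe(remaining, min(target - length(sel),
                                                 length(remaining))))
      }
      ids <- sprintf("%s_SB_%02d", pop, seq_along(sel))
      mats[[pop]] <- band_phenotype(bank$a1[sel, , drop = FALSE],
                                    bank$a2[sel, , drop = FALSE])
      rownames(mats[[pop]]) <- ids
      tr <- tray_of_seed[sel]
      metas[[pop]] <- data.frame(
        sample_id = ids, population = pop, region = layout$region[i],
        habitat = layout$habitat[i], cohort = "SB",
        x = (chosen[trays[tr, 1L], 1L] + chosen[trays[tr, 2L], 1L]) / 2,
        y = (chosen[trays[tr, 1L], 2L] + chosen[trays[tr, 2L], 2L]) / 2,
        tray_id = sprintf("%s_T%02d", pop, tr),
        tray_x1 = chosen[trays[tr, 1L], 1L],
        tray_y1 = chosen[trays[tr, 1L], 2L],
        tray_x2 = chosen[trays[tr, 2L], 1L],
        tray_y2 = chosen[trays[tr, 2L], 2L],
        stringsAsFactors = FALSE)
      core_area <- cores_per_cell * take * pi * (core_diameter / 2)^2
      counts[[pop]] <- data.frame(
        population = pop, n_trays = nrow(trays),
        seedlings = length(germ),
        seedlings_per_m2 = seedling_density(length(germ), core_area))
    }
    values <- do.call(rbind, mats)
    colnames(values) <- sprintf("L%03d", seq_len(ncol(values)))
    list(markers = marker_matrix(values),
         samples = sample_table(do.call(rbind, metas)),
         seedling_counts = do.call(rbind, counts))
  })
}

#' Simulate a complete two-cohort survey dataset
#'
#' Convenience wrapper: runs [simulate_metapopulation()] and both sampling
#' emulators, returning one combined marker matrix and sample table.
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed for the sampling stages (the simulation itself uses
#'   `cfg$seed`).
#' @return list with `markers`, `samples`, `dataset` (the `sim_dataset`),
#'   `ag_flags`, `seedling_counts`.
#' @export
simulate_survey <- function(cfg, seed = cfg$seed) {
  ds <- simulate_metapopulation(cfg)
  ag <- sample_aboveground(ds, seed = derive_seed(seed, 11L))
  sb <- sample_seed_bank(ds, seed = derive_seed(seed, 12L))
  values <- rbind(unclass(ag$markers), unclass(sb$markers))
  samples <- merge_sample_tables(ag$samples, sb$samples)
  list(markers = marker_matrix(values), samples = samples, dataset = ds,
       ag_flags = ag$flags, seedling_counts = sb$seedling_counts)
}

merge_sample_tables <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  sample_table(rbind(a[names(a)], b[names(a)]))
}
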