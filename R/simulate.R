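#' Default population layout of the emulated survey
#'
#' Fifteen populations in two regions (R, T) by two habitats: four meadow
#' and three woodland populations in region R, three meadow and five
#' woodland populations in region T.
#'
#' @return data.frame with `population`, `region`, `habitat`.
#' @export
default_population_layout <- function() {
  data.frame(
    population = c("RM1", "RM2", "RM3", "RM4", "RW1", "RW2", "RW3",
                   "TM1", "TM2", "TM3", "TW1", "TW2", "TW3", "TW4", "TW5"),
    region = c(rep("R", 7), rep("T", 8)),
    habitat = c(rep("meadow", 4), rep("woodland", 3),
                rep("meadow", 3), rep("woodland", 5)),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the forward metapopulation simulator
#'
#' Defaults emulate the motivating field survey: 15 populations on 1-m
#' grids, 528 dominant diallelic loci of which about 24% segregate, very
#' high selfing in meadow habitats (0.96) and substantially lower selfing
#' in woodland habitats (0.70, reflecting shade-induced outcrossing),
#' short seed dispersal (sigma 1.3 m), strong among-population divergence
#' (F-model parameter 0.8 on founder frequencies) and no migration.  The
#' seed bank follows geometric survival (0.5 per year, maximum age 10),
#' a free parameter of the generator.
#'
#' @param populations data.frame with `population`, `region`, `habitat`.
#' @param n_loci number of dominant diallelic loci.
#' @param frac_polymorphic fraction of loci with a segregating founder
#'   band-allele frequency (drawn uniform on \[0.1, 0.9\]); the remainder
#'   are fixed for the band.
#' @param divergence F-model drift parameter in \[0, 1) applied to founder
#'   frequencies per population (0 = identical founders).
#' @param selfing_rate,sigma_pollen,sigma_seed,capacity named vectors with
#'   entries `meadow` and `woodland`: selfing probability, Gaussian pollen
#'   and seed dispersal sigmas (m), and adult carrying capacity.
#' @param grid_extent side length of the square population grid (m).
#' @param n_generations number of non-overlapping adult generations.
#' @param seeds_per_adult seeds produced per adult per generation.
#' @param bank_survival per-year survival probability of banked seeds.
#' @param bank_max_age maximum seed age (years) in the bank.
#' @param mutation_rate per-allele, per-generation flip probability.
#' @param seed RNG seed for the whole simulation.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(populations = default_population_layout(),
                              n_loci = 528L, frac_polymorphic = 0.24,
                              divergence = 0.8,
                              selfing_rate = c(meadow = 0.96, woodland = 0.70),
                              sigma_pollen = c(meadow = 5, woodland = 5),
                              sigma_seed = c(meadow = 1.3, woodland = 1.3),
                              capacity = c(meadow = 150, woodland = 60),
                              grid_extent = 20, n_generations = 30L,
                              seeds_per_adult = 5L, bank_survival = 0.5,
                              bank_max_age = 10L, mutation_rate = 1e-4,
                              seed = 1L) {
  cfg <- list(populations = populations, n_loci = as.integer(n_loci),
              frac_polymorphic = frac_polymorphic, divergence = divergence,
              selfing_rate = selfing_rate, sigma_pollen = sigma_pollen,
              sigma_seed = sigma_seed, capacity = capacity,
              grid_extent = grid_extent,
              n_generations = as.integer(n_generations),
              seeds_per_adult = as.integer(seeds_per_adult),
              bank_survival = bank_survival,
              bank_max_age = as.integer(bank_max_age),
              mutation_rate = mutation_rate, seed = seed)
  rates <- c(cfg$frac_polymorphic, cfg$divergence, cfg$selfing_rate,
             cfg$bank_survival, cfg$mutation_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$divergence >= 1) stop("divergence must be < 1", call. = FALSE)
  if (any(c(cfg$sigma_pollen, cfg$sigma_seed) < 0)) {
    stop("dispersal sigmas must be non-negative", call. = FALSE)
  }
  if (any(cfg$capacity < 2)) stop("capacities must be at least 2", call. = FALSE)
  needed <- unique(populations$habitat)
  for (f in c("selfing_rate", "sigma_pollen", "sigma_seed", "capacity")) {
    if (!all(needed %in% names(cfg[[f]]))) {
      stop(sprintf("%s must be named for habitat(s): %s", f,
                   paste(needed, collapse = ", ")), call. = FALSE)
    }
  }
  structure(cfg, class = "simulation_config")
}

#' Habitat presets for the simulator
#'
#' `"meadow"`: selfing 0.96, larger capacity; `"woodland"`: selfing 0.70,
#' smaller capacity; both with seed dispersal sigma 1.3 m and pollen
#' dispersal sigma 5 m.  The returned config contains only that habitat's
#' populations from the default layout.
#'
#' @param habitat `"meadow"` or `"woodland"`.
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
presets <- function(habitat = c("meadow", "woodland"), ...) {
  habitat <- match.arg(habitat)
  layout <- default_population_layout()
  simulation_config(populations = layout[layout$habitat == habitat, ], ...)
}

# reflectless boundary handling: re-draw Gaussian displacements that leave
# the grid; after `max_tries` the position is clamped to the boundary
disperse <- function(x0, y0, sigma, extent, max_tries = 20L) {
  n <- length(x0)
  x <- x0 + stats::rnorm(n, 0, sigma)
  y <- y0 + stats::rnorm(n, 0, sigma)
  for (it in seq_len(max_tries)) {
    out <- which(x < 0 | x > extent | y < 0 | y > extent)
    if (!length(out)) break
    x[out] <- x0[out] + stats::rnorm(length(out), 0, sigma)
    y[out] <- y0[out] + stats::rnorm(length(out), 0, sigma)
  }
  cbind(pmin(pmax(x, 0), extent), pmin(pmax(y, 0), extent))
}

# maternal/paternal gamete: one allele per locus, uniformly
gamete <- function(a1, a2, rows) {
  g1 <- a1[rows, , drop = FALSE]
  g2 <- a2[rows, , drop = FALSE]
  pick <- matrix(stats::runif(length(g1)) < 0.5, nrow(g1), ncol(g1))
  out <- g2
  out[pick] <- g1[pick]
  out
}

mutate_alleles <- function(g, mu) {
  if (mu <= 0) return(g)
  flips <- matrix(stats::runif(length(g)) < mu, nrow(g), ncol(g))
  (g + flips) %% 2L
}

simulate_population <- function(pop, habitat, cfg, p_pop) {
  K <- as.integer(cfg$capacity[[habitat]])
  L <- cfg$n_loci
  s_rate <- cfg$selfing_rate[[habitat]]
  sp <- cfg$sigma_pollen[[habitat]]
  ss <- cfg$sigma_seed[[habitat]]
  extent <- cfg$grid_extent
  spa <- cfg$seeds_per_adult

  a1 <- matrix(stats::rbinom(K * L, 1L, rep(p_pop, each = K)), K, L)
  a2 <- matrix(stats::rbinom(K * L, 1L, rep(p_pop, each = K)), K, L)
  px <- stats::runif(K, 0, extent)
  py <- stats::runif(K, 0, extent)
  adult_selfed <- rep(NA, K)

  bank <- list(a1 = matrix(0L, 0L, L), a2 = matrix(0L, 0L, L),
               x = numeric(0), y = numeric(0), age = integer(0),
               selfed = logical(0))
  realized_selfing <- numeric(cfg$n_generations)

  age_bank <- function(bank) {
    if (!length(bank$age)) return(bank)
    live <- which(stats::runif(length(bank$age)) < cfg$bank_survival &
                    bank$age + 1L <= cfg$bank_max_age)
    list(a1 = bank$a1[live, , drop = FALSE], a2 = bank$a2[live, , drop = FALSE],
         x = bank$x[live], y = bank$y[live], age = bank$age[live] + 1L,
         selfed = bank$selfed[live])
  }

  for (t in seq_len(cfg$n_generations)) {
    bank <- age_bank(bank)
    n_ad <- nrow(a1)
    n_seeds <- n_ad * spa
    mom <- rep(seq_len(n_ad), each = spa)
    selfed <- stats::runif(n_seeds) < s_rate
    dad <- mom
    out_idx <- which(!selfed)
    if (length(out_idx) && n_ad > 1L) {
      dmat <- as.matrix(stats::dist(cbind(px, py)))
      w <- exp(-dmat^2 / (2 * sp^2))
      diag(w) <- 0
      for (mm in unique(mom[out_idx])) {
        sel <- out_idx[mom[out_idx] == mm]
        if (sum(w[mm, ]) <= 0) { selfed[sel] <- TRUE; dad[sel] <- mm; next }
        dad[sel] <- sample.int(n_ad, length(sel), replace = TRUE,
                               prob = w[mm, ])
      }
    } else if (length(out_idx)) {
      selfed[out_idx] <- TRUE
    }
    g1 <- mutate_alleles(gamete(a1, a2, mom), cfg$mutation_rate)
    g2 <- mutate_alleles(gamete(a1, a2, dad), cfg$mutation_rate)
    pos <- disperse(px[mom], py[mom], ss, extent)
    realized_selfing[t] <- mean(selfed)

    n_bank <- length(bank$age)
    pool_n <- n_seeds + n_bank
    if (pool_n < 2L) {
      stop(sprintf("population %s went extinct at generation %d", pop, t),
           call. = FALSE)
    }
    recruits <- sample.int(pool_n, min(K, pool_n))
    from_new <- recruits[recruits <= n_seeds]
    from_bank <- recruits[recruits > n_seeds] - n_seeds
    a1 <- rbind(g1[from_new, , drop = FALSE],
                bank$a1[from_bank, , drop = FALSE])
    a2 <- rbind(g2[from_new, , drop = FALSE],
                bank$a2[from_bank, , drop = FALSE])
    px <- c(pos[from_new, 1L], bank$x[from_bank])
    py <- c(pos[from_new, 2L], bank$y[from_bank])
    adult_selfed <- c(selfed[from_new], bank$selfed[from_bank])

    left_new <- setdiff(seq_len(n_seeds), from_new)
    left_bank <- setdiff(seq_len(n_bank), from_bank)
    bank <- list(
      a1 = rbind(bank$a1[left_bank, , drop = FALSE],
                 g1[left_new, , drop = FALSE]),
      a2 = rbind(bank$a2[left_bank, , drop = FALSE],
                 g2[left_new, , drop = FALSE]),
      x = c(bank$x[left_bank], pos[left_new, 1L]),
      y = c(bank$y[left_bank], pos[left_new, 2L]),
      age = c(bank$age[left_bank], rep(0L, length(left_new))),
      selfed = c(bank$selfed[left_bank], selfed[left_new]))
  }
  # final aging step so all stored seeds have age >= 1
  bank <- age_bank(bank)
  list(adults = list(a1 = a1, a2 = a2, x = px, y = py, selfed = adult_selfed),
       bank = bank,
       truth = list(realized_selfing = mean(realized_selfing),
                    bank_ages = bank$age))
}

#' Forward simulation of a selfing, seed-banking metapopulation
#'
#' Per generation and population: each adult produces seeds, selfed with
#' the habitat's selfing probability or otherwise sired by a pollen donor
#' drawn with Gaussian kernel weights; seeds disperse by a Gaussian kernel
#' around the mother; recruitment refills the carrying capacity from the
#' current seed rain plus germinating banked seeds; unrecruited seeds enter
#' the bank, surviving each year with fixed probability up to a maximum
#' age.  Loci are diploid and diallelic; the emitted marker state is the
#' dominant band phenotype (band present iff at least one dominant allele).
#' Populations exchange no migrants.
#'
#' @param cfg a [simulation_config()].
#' @return a `sim_dataset`: per-population adults (AG candidates), seed bank
#'   (stored seeds of age >= 1), a truth record (realized selfing, bank age
#'   distribution, founder frequencies) and the config.
#' @export
simulate_metapopulation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n_poly <- round(cfg$frac_polymorphic * cfg$n_loci)
    p_global <- c(stats::runif(n_poly, 0.1, 0.9),
                  rep(1, cfg$n_loci - n_poly))
    pops <- vector("list", nrow(cfg$populations))
    names(pops) <- cfg$populations$population
    for (i in seq_len(nrow(cfg$populations))) {
      pop <- cfg$populations$population[i]
      habitat <- cfg$populations$habitat[i]
      d <- cfg$divergence
      p_pop <- if (d > 0) {
        vapply(p_global, function(p) {
          if (p <= 0 || p >= 1) return(p)
          stats::rbeta(1L, p * (1 - d) / d, (1 - p) * (1 - d) / d)
        }, numeric(1))
      } else p_global
      pops[[pop]] <- simulate_population(pop, habitat, cfg, p_pop)
      pops[[pop]]$founder_freq <- p_pop
    }
    structure(list(populations = pops, cfg = cfg,
                   truth = list(
                     realized_selfing = vapply(pops, function(p)
                       p$truth$realized_selfing, numeric(1)),
                     bank_age_distribution = table(unlist(lapply(pops, function(p)
                       p$truth$bank_ages))))),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d populations, %d loci, %d generations\n",
              length(x$populations), x$cfg$n_loci, x$cfg$n_generations))
  cat(sprintf("  realized selfing: %.3f-%.3f; bank sizes: %s\n",
              min(x$truth$realized_selfing), max(x$truth$realized_selfing),
              paste(range(vapply(x$populations, function(p)
                length(p$bank$age), numeric(1))), collapse = "-")))
  invisible(x)
}

band_phenotype <- function(a1, a2) {
  p <- (a1 | a2) * 1L
  storage.mode(p) <- "integer"
  p
}
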