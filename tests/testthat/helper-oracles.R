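# independent oracles used across tests: Monte-Carlo rarefaction,
# scalar-loop kinship, and a loop-based hierarchical AMOVA

random_binary_matrix <- function(n, L, seed) {
  set.seed(seed)
  v <- matrix(rbinom(n * L, 1L, runif(L, 0.2, 0.8)[rep(seq_len(L), each = n)]),
              n, L)
  rownames(v) <- paste0("s", seq_len(n))
  colnames(v) <- paste0("L", seq_len(L))
  v
}

# Monte-Carlo subsampling estimates (mean and standard error) of the
# rarefied statistics, by literally drawing g rows without replacement
mc_band_richness <- function(v, g, R = 2000L, seed = 1L) {
  set.seed(seed)
  draws <- vapply(seq_len(R), function(r) {
    cs <- colSums(v[sample.int(nrow(v), g), , drop = FALSE])
    mean((cs > 0) + (cs < g))
  }, numeric(1))
  c(mean = mean(draws), se = sd(draws) / sqrt(R))
}

mc_emlg <- function(v, g, R = 2000L, seed = 1L) {
  set.seed(seed)
  draws <- vapply(seq_len(R), function(r) {
    sub <- v[sample.int(nrow(v), g), , drop = FALSE]
    length(unique(apply(sub, 1L, paste, collapse = "")))
  }, numeric(1))
  c(mean = mean(draws), se = sd(draws) / sqrt(R))
}

mc_private_bands <- function(va, vb, g, R = 2000L, seed = 1L) {
  set.seed(seed)
  draws <- vapply(seq_len(R), function(r) {
    sa <- va[sample.int(nrow(va), g), , drop = FALSE]
    sb <- vb[sample.int(nrow(vb), g), , drop = FALSE]
    sum(colSums(sa) > 0 & colSums(sb) == 0)
  }, numeric(1))
  c(mean = mean(draws), se = sd(draws) / sqrt(R))
}

# scalar-loop coding of the dominant-marker kinship estimator
oracle_kinship <- function(v, inbreeding_f) {
  n <- nrow(v); L <- ncol(v)
  fr <- colMeans(v)
  dens <- numeric(L); use <- logical(L)
  for (l in seq_len(L)) {
    h <- 1 - fr[l]
    if (h <= 0 || h >= 1) next
    q <- if (inbreeding_f == 0) sqrt(h) else
      (-inbreeding_f + sqrt(inbreeding_f^2 + 4 * (1 - inbreeding_f) * h)) /
      (2 * (1 - inbreeding_f))
    if (q < 0 || q > 1) next
    p <- 1 - q
    dens[l] <- 4 * p * q * (q + inbreeding_f * p)^2
    use[l] <- TRUE
  }
  k <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (l in which(use)) s <- s + (v[i, l] - fr[l]) * (v[j, l] - fr[l])
      k[i, j] <- s / sum(dens[use])
    }
  }
  k
}

# loop-based hierarchical AMOVA solving the expected-mean-square system
oracle_amova_hier <- function(d, regions, pops) {
  N <- nrow(d)
  ssd <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d[i, j]
    s / (2 * length(idx))
  }
  pops_u <- unique(pops); regs_u <- unique(regions)
  sst <- ssd(seq_len(N))
  ssw <- sum(vapply(pops_u, function(p) ssd(which(pops == p)), numeric(1)))
  ssr <- sum(vapply(regs_u, function(r) ssd(which(regions == r)), numeric(1)))
  SS <- c(sst - ssr, ssr - ssw, ssw)
  df <- c(length(regs_u) - 1L, length(pops_u) - length(regs_u),
          N - length(pops_u))
  MS <- SS / df
  npop <- vapply(pops_u, function(p) sum(pops == p), numeric(1))
  regof <- vapply(pops_u, function(p) regions[which(pops == p)[1L]],
                  character(1))
  Nr <- vapply(regs_u, function(r) sum(regions == r), numeric(1))
  a <- sum(vapply(seq_along(regs_u), function(k) {
    sum(npop[regof == regs_u[k]]^2) / Nr[k]
  }, numeric(1)))
  n1 <- (N - a) / df[2L]
  n2 <- (a - sum(npop^2) / N) / df[1L]
  n3 <- (N - sum(Nr^2) / N) / df[1L]
  A <- rbind(c(n3, n2, 1), c(0, n1, 1), c(0, 0, 1))
  sigma <- solve(A, MS)
  list(sigma = sigma,
       phi_ct = sigma[1L] / sum(sigma),
       phi_sc = sigma[2L] / (sigma[2L] + sigma[3L]),
       phi_st = (sigma[1L] + sigma[2L]) / sum(sigma))
}

# small simulated single-population AG dataset used by several suites
sim_one_pop <- function(selfing = 0.96, n_loci = 150, capacity = 60,
                        n_generations = 15, seed = 42) {
  layout <- data.frame(population = "P1", region = "R", habitat = "meadow")
  cfg <- simulation_config(populations = layout, n_loci = n_loci,
                           selfing_rate = c(meadow = selfing),
                           sigma_pollen = c(meadow = 5),
                           sigma_seed = c(meadow = 1.3),
                           capacity = c(meadow = capacity),
                           n_generations = n_generations, seed = seed)
  simulate_metapopulation(cfg)
}
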