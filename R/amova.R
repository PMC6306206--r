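#' Pairwise squared Euclidean distances between band phenotypes
#'
#' For 0/1 phenotypes the squared Euclidean distance equals the number of
#' loci at which two individuals differ, the standard AMOVA metric for
#' binary data.
#'
#' @param m a [marker_matrix()].
#' @return symmetric n x n numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(m) {
  v <- unclass(m)
  cross <- tcrossprod(v)
  n1 <- rowSums(v)
  d <- outer(n1, n1, "+") - 2 * cross
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

ss_total <- function(d) sum(d[upper.tri(d)]) / nrow(d)

ss_within_groups <- function(d, groups) {
  sum(vapply(split(seq_len(nrow(d)), groups), function(idx) {
    sub <- d[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
}

phi_from_components <- function(va, vw) va / (va + vw)

amova_oneway_components <- function(d, groups) {
  groups <- as.factor(groups)
  N <- nrow(d)
  sizes <- table(groups)
  G <- length(sizes)
  sst <- ss_total(d)
  ssw <- ss_within_groups(d, groups)
  ssa <- sst - ssw
  df_a <- G - 1L
  df_w <- N - G
  ms_a <- ssa / df_a
  ms_w <- ssw / df_w
  # n0: effective group size coefficient for unbalanced designs,
  # (N - sum(n_g^2)/N) / (G - 1)
  n0 <- (N - sum(sizes^2) / N) / df_a
  vw <- ms_w
  va <- (ms_a - ms_w) / n0
  list(ss = c(among = ssa, within = ssw, total = sst),
       df = c(among = df_a, within = df_w),
       ms = c(among = ms_a, within = ms_w),
       sigma = c(among = va, within = vw),
       phi_st = phi_from_components(va, vw))
}

#' One-way AMOVA with permutation test
#'
#' Excoffier-style analysis of molecular variance from a squared-distance
#' matrix: partitions variance among and within groups, reports phi-ST and a
#' permutation p-value obtained by permuting individuals among groups with
#' the `(hits + 1)/(n_perm + 1)` estimator.  Negative variance components
#' are retained by default (set `truncate = TRUE` to clamp at zero).
#'
#' @param d distance matrix from [pairwise_distance()].
#' @param groups vector of group labels, one per row of `d`; at least two
#'   groups with at least two members each.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @param truncate clamp negative variance components to zero.
#' @return an `amova_result`: `levels` data.frame (source, df, SS, variance
#'   component, percentage of total, p), `phi_st`, `n_permutations`.
#' @export
amova_oneway <- function(d, groups, n_perm = 9999L, seed = 1L,
                         truncate = FALSE) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 members (singleton group found)",
         call. = FALSE)
  }
  obs <- amova_oneway_components(d, groups)
  sigma <- obs$sigma
  if (truncate) sigma <- pmax(sigma, 0)
  total <- sum(sigma)
  p <- NA_real_
  if (n_perm > 0L) {
    perm_phi <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        amova_oneway_components(d, groups[sample.int(length(groups))])$phi_st
      }, numeric(1))
    })
    p <- (sum(perm_phi >= obs$phi_st - 1e-12) + 1) / (n_perm + 1)
  }
  levels_df <- data.frame(
    source = c("Among groups", "Within groups"),
    df = obs$df,
    SS = obs$ss[c("among", "within")],
    sigma = sigma,
    pct_total = 100 * sigma / total,
    p = c(p, NA_real_),
    row.names = NULL
  )
  structure(list(levels = levels_df, phi_st = obs$phi_st,
                 n_permutations = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$levels, row.names = FALSE, digits = 4)
  phis <- x[intersect(c("phi_st", "phi_sc", "phi_ct"), names(x))]
  cat(paste(sprintf("%s = %.4f", toupper(names(phis)),
                    unlist(phis)), collapse = ", "), "\n")
  invisible(x)
}

amova_hier_components <- function(d, regions, populations) {
  regions <- as.character(regions)
  populations <- as.character(populations)
  N <- nrow(d)
  pop_sizes <- table(populations)
  P <- length(pop_sizes)
  region_of_pop <- tapply(regions, populations, function(z) z[1L])
  reg_sizes <- table(regions)
  R <- length(reg_sizes)
  sst <- ss_total(d)
  ssw <- ss_within_groups(d, populations)          # within populations
  ssr <- ss_within_groups(d, regions)              # within regions (total)
  ss_ap <- ssr - ssw                                # among pops within regions
  ss_ar <- sst - ssr                                # among regions
  df_ar <- R - 1L
  df_ap <- P - R
  df_wp <- N - P
  ms_ar <- ss_ar / df_ar
  ms_ap <- ss_ap / df_ap
  ms_wp <- ssw / df_wp
  # Unbalanced-design coefficients (standard nested ANOVA on distances):
  #   n   = [N - sum_r(sum_{p in r} n_p^2 / N_r)] / (P - R)
  #   n'  = [sum_r(sum_{p in r} n_p^2 / N_r) - sum_p n_p^2 / N] / (R - 1)
  #   n'' = [N - sum_r N_r^2 / N] / (R - 1)
  # sum over regions of (sum of n_p^2 within region) / N_r
  a_term <- sum(vapply(names(reg_sizes), function(r) {
    np <- as.numeric(pop_sizes[names(region_of_pop)[region_of_pop == r]])
    sum(np^2) / sum(np)
  }, numeric(1)))
  n_coef <- (N - a_term) / df_ap
  np_coef <- (a_term - sum(as.numeric(pop_sizes)^2) / N) / df_ar
  npp_coef <- (N - sum(as.numeric(reg_sizes)^2) / N) / df_ar
  vc <- ms_wp
  vb <- (ms_ap - vc) / n_coef
  va <- (ms_ar - vc - np_coef * vb) / npp_coef
  total <- va + vb + vc
  list(ss = c(among_regions = ss_ar, among_pops = ss_ap, within = ssw),
       df = c(among_regions = df_ar, among_pops = df_ap, within = df_wp),
       sigma = c(among_regions = va, among_pops = vb, within = vc),
       phi_ct = va / total,
       phi_sc = vb / (vb + vc),
       phi_st = (va + vb) / total)
}

#' Hierarchical (two-level) AMOVA with permutation tests
#'
#' Partitions variance among regions, among populations within regions and
#' within populations, with the standard permutation scheme per component:
#' whole populations permuted among regions for phi-CT, individuals among
#' populations within their region for phi-SC, and individuals among all
#' populations for phi-ST.
#'
#' @param d distance matrix from [pairwise_distance()].
#' @param regions,populations label vectors, one per row of `d`; populations
#'   must nest within regions.
#' @param n_perm number of permutations per test (0 skips).
#' @param seed RNG seed.
#' @return an `amova_result` with `levels`, `phi_st`, `phi_sc`, `phi_ct`.
#'   A region containing a single population is flagged via the
#'   `degenerate` attribute (phi-CT is still computed but unstable).
#' @export
amova_hierarchical <- function(d, regions, populations, n_perm = 9999L,
                               seed = 1L) {
  regions <- as.character(regions)
  populations <- as.character(populations)
  region_of_pop <- tapply(regions, populations, function(z) {
    if (length(unique(z)) > 1L) stop("population spans regions", call. = FALSE)
    z[1L]
  })
  if (length(unique(regions)) < 2L) {
    stop("hierarchical AMOVA needs at least 2 regions", call. = FALSE)
  }
  degenerate <- any(table(region_of_pop) < 2L)
  if (degenerate) {
    warning("a region contains a single population; phi_CT flagged unstable",
            call. = FALSE)
  }
  obs <- amova_hier_components(d, regions, populations)
  n <- nrow(d)
  p_ct <- p_sc <- p_st <- NA_real_
  if (n_perm > 0L) {
    pops <- unique(populations)
    pop_region <- region_of_pop[pops]
    perms <- with_seed(seed, {
      hits_ct <- hits_sc <- hits_st <- 0L
      for (b in seq_len(n_perm)) {
        # phi_ST: individuals among all populations
        perm_pop <- populations[sample.int(n)]
        st <- amova_hier_components(d, region_of_pop[perm_pop], perm_pop)
        if (st$phi_st >= obs$phi_st - 1e-12) hits_st <- hits_st + 1L
        # phi_SC: individuals among populations within regions
        perm_sc <- populations
        for (r in unique(regions)) {
          idx <- which(regions == r)
          perm_sc[idx] <- perm_sc[idx][sample.int(length(idx))]
        }
        sc <- amova_hier_components(d, regions, perm_sc)
        if (sc$phi_sc >= obs$phi_sc - 1e-12) hits_sc <- hits_sc + 1L
        # phi_CT: whole populations among regions
        perm_reg_of_pop <- stats::setNames(pop_region[sample.int(length(pops))],
                                           pops)
        ct <- amova_hier_components(d, perm_reg_of_pop[populations], populations)
        if (ct$phi_ct >= obs$phi_ct - 1e-12) hits_ct <- hits_ct + 1L
      }
      c(ct = hits_ct, sc = hits_sc, st = hits_st)
    })
    p_ct <- (perms[["ct"]] + 1) / (n_perm + 1)
    p_sc <- (perms[["sc"]] + 1) / (n_perm + 1)
    p_st <- (perms[["st"]] + 1) / (n_perm + 1)
  }
  sigma <- obs$sigma
  total <- sum(sigma)
  levels_df <- data.frame(
    source = c("Among regions", "Among populations within regions",
               "Within populations"),
    df = obs$df,
    SS = obs$ss,
    sigma = sigma,
    pct_total = 100 * sigma / total,
    p = c(p_ct, p_sc, p_st),
    row.names = NULL
  )
  structure(list(levels = levels_df, phi_st = obs$phi_st,
                 phi_sc = obs$phi_sc, phi_ct = obs$phi_ct,
                 n_permutations = n_perm, degenerate = degenerate),
            class = "amova_result")
}

#' Pairwise phi-ST matrices with permutation p-values
#'
#' Applies [amova_oneway()] to every pair of groups.  `pairing =
#' "population"` compares populations; `pairing = "cohort"` compares the AG
#' and SB cohorts within each population.  No multiplicity correction is
#' applied by default; set `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param m a [marker_matrix()].
#' @param s a [sample_table()].
#' @param pairing `"population"` or `"cohort"`.
#' @param n_perm,seed permutation settings per pair.
#' @param p_adjust `"none"` (default) or any `stats::p.adjust` method.
#' @return data.frame with one row per pair: `group_a, group_b, phi_st, p`
#'   (plus `p_adj` when requested).  For `pairing = "population"` the
#'   `phi_matrix` attribute carries the square matrix.
#' @export
pairwise_phi_st <- function(m, s, pairing = c("population", "cohort"),
                            n_perm = 9999L, seed = 1L, p_adjust = "none") {
  pairing <- match.arg(pairing)
  s <- align_samples(m, s)
  rows <- list()
  if (pairing == "population") {
    pops <- sort(unique(s$population))
    for (i in seq_along(pops)) {
      for (j in seq_len(i - 1L)) {
        ids <- s$sample_id[s$population %in% pops[c(i, j)]]
        sub <- subset_samples(m, ids)
        grp <- s$population[match(ids, s$sample_id)]
        res <- amova_oneway(pairwise_distance(sub), grp, n_perm = n_perm,
                            seed = derive_seed(seed, i * 1000L + j))
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = pops[j], group_b = pops[i],
          phi_st = res$phi_st, p = res$levels$p[1L])
      }
    }
  } else {
    for (pop in sort(unique(s$population))) {
      sub_s <- s[s$population == pop, ]
      if (length(unique(sub_s$cohort)) < 2L ||
          any(table(sub_s$cohort) < 2L)) {
        warning(sprintf("%s: cohort missing or singleton; pair skipped", pop),
                call. = FALSE)
        next
      }
      sub <- subset_samples(m, sub_s$sample_id)
      res <- amova_oneway(pairwise_distance(sub), sub_s$cohort,
                          n_perm = n_perm,
                          seed = derive_seed(seed, match(pop, unique(s$population))))
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = paste0(pop, "_AG"), group_b = paste0(pop, "_SB"),
        phi_st = res$phi_st, p = res$levels$p[1L])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  if (pairing == "population") {
    pops <- sort(unique(s$population))
    mat <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
    diag(mat) <- 0
    for (k in seq_len(nrow(out))) {
      mat[out$group_a[k], out$group_b[k]] <- out$phi_st[k]
      mat[out$group_b[k], out$group_a[k]] <- out$phi_st[k]
    }
    attr(out, "phi_matrix") <- mat
  }
  out
}

#' Principal component analysis of a binary marker matrix
#'
#' Eigendecomposition of the covariance of the column-centered 0/1 matrix.
#' Columns are centered but not scaled: with binary data, unit scaling would
#' upweight rare bands.
#'
#' @param m a [marker_matrix()].
#' @param n_components number of components to retain (default all).
#' @return a `pca_result`: `scores` (individuals x components),
#'   `variance_fraction` per component, `n_components`.
#' @export
pca_scores <- function(m, n_components = NULL) {
  v <- unclass(m)
  centered <- scale(v, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    k <- min(dim(v))
    return(structure(list(scores = matrix(0, nrow(v), k,
                                          dimnames = list(rownames(v), NULL)),
                          variance_fraction = rep(0, k), n_components = k),
                     class = "pca_result"))
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) length(varfrac) else
    min(n_components, length(varfrac))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 variance_fraction = varfrac[seq_len(k)],
                 n_components = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; leading variance fractions: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%",
                            100 * utils::head(x$variance_fraction, 3L)),
                    collapse = ", ")))
  invisible(x)
}
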