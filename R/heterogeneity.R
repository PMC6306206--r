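#' Correlogram heterogeneity test between two groups
#'
#' Tests whether two groups (e.g. habitats, or the AG and SB cohorts)
#' differ in their kinship correlograms, per distance class (squared
#' standardized difference t2) and overall (omega = sum of the per-class
#' t2 over classes non-empty in both groups).  Each group is a list with a
#' `markers` [marker_matrix()], a `coords` data.frame (`x`, `y`) and
#' optionally a `populations` vector; kinship is computed per population
#' (its own reference band frequencies) and only within-population pairs
#' enter the class means, so pooled multi-population groups are supported.
#'
#' The null distribution permutes multilocus genotypes across spatial
#' positions within each population; the per-class difference is
#' standardized by its permutation variance, and p-values use the
#' `(hits + 1)/(n_perm + 1)` estimator.  Following the usual convention
#' for this family of tests, overall significance is declared at
#' `p < alpha` with `alpha = 0.01`.  A pair bootstrap (within group and
#' class) supplies confidence bars for the class means.
#'
#' @param group_a,group_b lists with elements `markers`, `coords` and
#'   optionally `populations`.
#' @param class_limits distance class upper bounds (m).
#' @param n_perm permutations for the test; `n_boot` bootstraps for the
#'   class confidence bars (0 skips either).
#' @param seed RNG seed.
#' @param inbreeding_f assumed inbreeding coefficient for [kinship_matrix()].
#' @param alpha significance level for the overall flag.
#' @return a `heterogeneity_result`: `classes` data.frame (`upper`,
#'   `mean_a`, `mean_b`, `n_pairs_a`, `n_pairs_b`, `t2`, `p`, bootstrap
#'   bars), `omega`, `p_omega`, `significant`, `n_permutations`.
#' @export
heterogeneity_test <- function(group_a, group_b,
                               class_limits = c(4, 8, 12, 16, 20),
                               n_perm = 9999L, n_boot = 9999L, seed = 1L,
                               inbreeding_f = 0.5, alpha = 0.01) {
  ga <- prepare_het_group(group_a, inbreeding_f)
  gb <- prepare_het_group(group_b, inbreeding_f)
  nc <- length(class_limits)
  pa <- het_pairs(ga, class_limits)
  pb <- het_pairs(gb, class_limits)
  obs_a <- het_class_means(ga, pa, nc)
  obs_b <- het_class_means(gb, pb, nc)
  n_pairs_a <- tabulate(pa$class, nc)
  n_pairs_b <- tabulate(pb$class, nc)
  shared <- n_pairs_a > 0L & n_pairs_b > 0L
  if (!any(shared)) stop("no distance class occupied in both groups", call. = FALSE)
  if (any(!shared)) {
    warning(sprintf("%d class(es) empty in one group; excluded from omega",
                    sum(!shared)), call. = FALSE)
  }
  d_obs <- obs_a - obs_b
  t2 <- p_class <- rep(NA_real_, nc)
  omega <- p_omega <- NA_real_
  if (n_perm > 0L) {
    d_perm <- with_seed(derive_seed(seed, 1L), {
      vapply(seq_len(n_perm), function(b) {
        het_class_means(ga, pa, nc, permute = TRUE) -
          het_class_means(gb, pb, nc, permute = TRUE)
      }, numeric(nc))
    })
    d_perm <- matrix(d_perm, nrow = nc)
    v <- apply(d_perm, 1L, stats::var)
    for (kk in which(shared)) {
      if (!is.finite(v[kk]) || v[kk] <= 0) next
      t2[kk] <- d_obs[kk]^2 / v[kk]
      t2_perm <- d_perm[kk, ]^2 / v[kk]
      p_class[kk] <- (sum(t2_perm >= t2[kk] - 1e-12) + 1) / (n_perm + 1)
    }
    use <- shared & is.finite(t2)
    omega <- sum(t2[use])
    omega_perm <- colSums((d_perm[use, , drop = FALSE]^2) / v[use])
    p_omega <- (sum(omega_perm >= omega - 1e-12) + 1) / (n_perm + 1)
  }
  boot <- het_bootstrap(ga, pa, gb, pb, nc, n_boot, derive_seed(seed, 2L))
  classes <- data.frame(upper = class_limits,
                        mean_a = obs_a, mean_b = obs_b,
                        n_pairs_a = n_pairs_a, n_pairs_b = n_pairs_b,
                        t2 = t2, p = p_class,
                        boot_low_a = boot$low_a, boot_high_a = boot$high_a,
                        boot_low_b = boot$low_b, boot_high_b = boot$high_b)
  structure(list(classes = classes, omega = omega, p_omega = p_omega,
                 significant = is.finite(p_omega) && p_omega < alpha,
                 alpha = alpha, n_permutations = n_perm),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> omega = %.3f, p = %s%s\n",
              x$omega, format.pval(x$p_omega),
              if (isTRUE(x$significant)) sprintf(" (significant at p < %.2f)",
                                                 x$alpha) else ""))
  print(x$classes[, c("upper", "mean_a", "mean_b", "t2", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

# per-population kinship (own reference frequencies) + located individuals
prepare_het_group <- function(group, inbreeding_f) {
  stopifnot(is.list(group), !is.null(group$markers), !is.null(group$coords))
  m <- group$markers
  coords <- group$coords
  pops <- if (is.null(group$populations)) rep("all", nrow(m)) else
    as.character(group$populations)
  keep <- which(is.finite(coords$x) & is.finite(coords$y))
  blocks <- split(keep, pops[keep])
  blocks <- blocks[lengths(blocks) >= 2L]
  if (!length(blocks)) stop("group has no population with 2 located individuals",
                            call. = FALSE)
  kin <- lapply(blocks, function(idx) {
    tryCatch(
      suppressWarnings(unclass(kinship_matrix(subset_samples(m, rownames(m)[idx]),
                                              inbreeding_f))),
      error = function(e) NULL)
  })
  ok <- !vapply(kin, is.null, logical(1))
  if (!any(ok)) stop("no population in the group yields a kinship matrix",
                     call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("%d population(s) dropped (no polymorphic loci for kinship)",
                    sum(!ok)), call. = FALSE)
  }
  list(kin = kin[ok],
       coords = lapply(blocks[ok], function(idx)
         coords[idx, c("x", "y"), drop = FALSE]))
}

# pair table per block: local indices (i, j) and distance class
het_pairs <- function(g, class_limits) {
  pairs <- lapply(seq_along(g$kin), function(b) {
    d <- pair_distances(g$coords[[b]])
    ut <- which(upper.tri(d), arr.ind = TRUE)
    cls <- distance_class(d[upper.tri(d)], class_limits)
    ok <- !is.na(cls)
    data.frame(block = b, i = ut[ok, 1L], j = ut[ok, 2L], class = cls[ok])
  })
  do.call(rbind, pairs)
}

het_class_means <- function(g, pairs, nc, permute = FALSE) {
  vals <- numeric(nrow(pairs))
  for (b in seq_along(g$kin)) {
    sel <- which(pairs$block == b)
    if (!length(sel)) next
    k <- g$kin[[b]]
    if (permute) {
      perm <- sample.int(nrow(k))
      vals[sel] <- k[cbind(perm[pairs$i[sel]], perm[pairs$j[sel]])]
    } else {
      vals[sel] <- k[cbind(pairs$i[sel], pairs$j[sel])]
    }
  }
  class_means(vals, pairs$class, nc)
}

het_bootstrap <- function(ga, pa, gb, pb, nc, n_boot, seed) {
  empty <- list(low_a = rep(NA_real_, nc), high_a = rep(NA_real_, nc),
                low_b = rep(NA_real_, nc), high_b = rep(NA_real_, nc))
  if (n_boot <= 0L) return(empty)
  boot_group <- function(g, pairs) {
    vals <- numeric(nrow(pairs))
    for (b in seq_along(g$kin)) {
      sel <- which(pairs$block == b)
      if (length(sel)) {
        vals[sel] <- g$kin[[b]][cbind(pairs$i[sel], pairs$j[sel])]
      }
    }
    lows <- highs <- rep(NA_real_, nc)
    for (kk in seq_len(nc)) {
      sel <- which(pairs$class == kk)
      if (length(sel) < 2L) next
      bm <- vapply(seq_len(n_boot), function(r) {
        mean(vals[sample(sel, length(sel), replace = TRUE)])
      }, numeric(1))
      qs <- stats::quantile(bm, c(0.025, 0.975))
      lows[kk] <- qs[1L]; highs[kk] <- qs[2L]
    }
    list(low = lows, high = highs)
  }
  with_seed(seed, {
    ba <- boot_group(ga, pa)
    bb <- boot_group(gb, pb)
    list(low_a = ba$low, high_a = ba$high, low_b = bb$low, high_b = bb$high)
  })
}
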