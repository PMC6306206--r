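#' Spatial coordinates for analysis, with seed-bank midpoint rule
#'
#' Aboveground samples keep their grid coordinates.  Seed-bank samples were
#' germinated from trays that pool the soil of two grid cells; a sample is
#' spatially eligible only if its tray's two source cells lie at most
#' `max_pool_span` metres apart, in which case it is placed at their
#' midpoint.  Trays with missing source coordinates are excluded with a
#' warning.
#'
#' @param s a [sample_table()]; SB rows should carry `tray_id` and source
#'   cell columns `tray_x1, tray_y1, tray_x2, tray_y2`.
#' @param max_pool_span maximum distance (m) between a tray's source cells.
#' @return data.frame `sample_id, x, y, eligible` (coordinates `NA` when
#'   ineligible).
#' @export
sb_coordinates <- function(s, max_pool_span = 4) {
  out <- data.frame(sample_id = s$sample_id, x = s$x, y = s$y,
                    eligible = TRUE, stringsAsFactors = FALSE)
  sb <- which(s$cohort == "SB")
  has_tray_cols <- all(c("tray_x1", "tray_y1", "tray_x2", "tray_y2") %in% names(s))
  for (i in sb) {
    if (!has_tray_cols || anyNA(as.numeric(s[i, c("tray_x1", "tray_y1",
                                                  "tray_x2", "tray_y2")]))) {
      warning(sprintf("%s: tray source coordinates missing; excluded from spatial analyses",
                      s$sample_id[i]), call. = FALSE)
      out$eligible[i] <- FALSE
      out$x[i] <- out$y[i] <- NA_real_
      next
    }
    x1 <- as.numeric(s$tray_x1[i]); y1 <- as.numeric(s$tray_y1[i])
    x2 <- as.numeric(s$tray_x2[i]); y2 <- as.numeric(s$tray_y2[i])
    span <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
    if (span > max_pool_span) {
      out$eligible[i] <- FALSE
      out$x[i] <- out$y[i] <- NA_real_
    } else {
      out$x[i] <- (x1 + x2) / 2
      out$y[i] <- (y1 + y2) / 2
    }
  }
  out
}

pair_distances <- function(coords) {
  as.matrix(stats::dist(coords[, c("x", "y")]))
}

# class index per pairwise distance: class 1 = [0, limits[1]],
# class k>1 = (limits[k-1], limits[k]]; beyond the last limit -> NA
distance_class <- function(d, class_limits) {
  idx <- findInterval(d, c(-1e-9, class_limits), left.open = TRUE)
  idx[idx > length(class_limits)] <- NA_integer_
  idx
}

class_means <- function(kvec, class_idx, n_classes) {
  vapply(seq_len(n_classes), function(k) {
    sel <- which(class_idx == k)
    if (length(sel)) mean(kvec[sel]) else NA_real_
  }, numeric(1))
}

#' Kinship correlogram over distance classes with permutation test
#'
#' Mean pairwise kinship per distance class (half-open classes
#' `(lower, upper]`, zero-distance pairs falling in the first class), with a
#' permutation null built by permuting multilocus genotypes across spatial
#' positions (equivalently, permuting kinship-matrix indices against the
#' coordinates).  Two-sided p-values use the `(hits + 1)/(n_perm + 1)`
#' estimator; empty classes are flagged rather than dropped.
#'
#' @param k a [kinship_matrix()].
#' @param coords data.frame with `x`, `y` for the same individuals, in row
#'   order of `k` (rows with `NA` coordinates are dropped).
#' @param class_limits upper bounds of the distance classes (m).
#' @param n_perm number of genotype permutations (0 skips the test).
#' @param seed RNG seed.
#' @return a `correlogram_result` data.frame: per class `upper`, `mean_fij`,
#'   `n_pairs`, `p`, `env_low`, `env_high`, `empty`.
#' @export
correlogram <- function(k, coords, class_limits = c(4, 8, 12, 16, 20),
                        n_perm = 9999L, seed = 1L) {
  keep <- which(is.finite(coords$x) & is.finite(coords$y))
  if (length(keep) < 2L) stop("need at least 2 located individuals", call. = FALSE)
  k <- unclass(k)[keep, keep, drop = FALSE]
  d <- pair_distances(coords[keep, , drop = FALSE])
  ut <- upper.tri(d)
  class_idx <- distance_class(d[ut], class_limits)
  kvec <- k[ut]
  nc <- length(class_limits)
  obs <- class_means(kvec, class_idx, nc)
  n_pairs <- vapply(seq_len(nc), function(kk) sum(class_idx == kk, na.rm = TRUE),
                    integer(1))
  p <- env_low <- env_high <- rep(NA_real_, nc)
  if (n_perm > 0L) {
    n <- nrow(k)
    perm_means <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n)
        class_means(k[idx, idx][ut], class_idx, nc)
      }, numeric(nc)))
    })
    for (kk in seq_len(nc)) {
      if (n_pairs[kk] == 0L) next
      pm <- perm_means[, kk]
      ge <- sum(pm >= obs[kk] - 1e-12) + 1
      le <- sum(pm <= obs[kk] + 1e-12) + 1
      p[kk] <- min(1, 2 * min(ge, le) / (n_perm + 1))
      qs <- stats::quantile(pm, c(0.025, 0.975), na.rm = TRUE)
      env_low[kk] <- qs[1L]
      env_high[kk] <- qs[2L]
    }
  }
  out <- data.frame(upper = class_limits, mean_fij = obs, n_pairs = n_pairs,
                    p = p, env_low = env_low, env_high = env_high,
                    empty = n_pairs == 0L)
  attr(out, "n_permutations") <- n_perm
  class(out) <- c("correlogram_result", "data.frame")
  out
}

#' Sp statistic from its kinship-regression ingredients
#'
#' `Sp = -b_log / (1 - F1)`, where `b_log` is the slope of pairwise kinship
#' on the natural log of distance and `F1` the mean kinship of the first
#' distance class.  Positive values indicate kinship decreasing with
#' distance, i.e. spatial genetic structure.
#'
#' @param F1 mean kinship in the first distance class (must differ from 1).
#' @param b_log regression slope of kinship on ln(distance).
#' @return the Sp statistic.
#' @examples
#' sp_statistic(F1 = 0.391, b_log = -0.428)  # 0.7029...
#' @export
sp_statistic <- function(F1, b_log) {
  if (any(abs(1 - F1) < 1e-12)) {
    stop("Sp undefined when F1 equals 1", call. = FALSE)
  }
  -b_log / (1 - F1)
}

#' Small-scale spatial genetic structure summary (F1, b_log, Sp)
#'
#' Restricted regression of pairwise kinship on ln(distance) over pairs with
#' `0 < distance <= max_dist`, the mean kinship of the first distance class
#' (co-located pairs included there but excluded from the log regression),
#' and `Sp = -b_log/(1 - F1)`.  Permutation p-values for both `F1` and
#' `b_log` come from permuting multilocus genotypes across positions.
#'
#' @param k a [kinship_matrix()].
#' @param coords data.frame with `x`, `y` per individual (rows with `NA`
#'   dropped).
#' @param max_dist regression restriction (m).
#' @param first_class_limit upper bound of the first distance class (m).
#' @param n_perm,seed permutation settings (`n_perm = 0` skips the test).
#' @param slope_on `"pairs"` (default; regression across individual pairs)
#'   or `"class_means"` (regression of class means on ln of class midpoint).
#' @param class_limits used only for `slope_on = "class_means"`.
#' @return an `sgs_summary` list: `n`, `F1`, `b_log`, `Sp`, `p_F1`,
#'   `p_b_log`, `n_pairs_first_class`, `n_pairs_regression`.
#' @export
sgs_summary <- function(k, coords, max_dist = 20, first_class_limit = 4,
                        n_perm = 9999L, seed = 1L,
                        slope_on = c("pairs", "class_means"),
                        class_limits = c(4, 8, 12, 16, 20)) {
  slope_on <- match.arg(slope_on)
  keep <- which(is.finite(coords$x) & is.finite(coords$y))
  if (length(keep) < 3L) stop("need at least 3 located individuals", call. = FALSE)
  k <- unclass(k)[keep, keep, drop = FALSE]
  d <- pair_distances(coords[keep, , drop = FALSE])
  ut <- upper.tri(d)
  dvec <- d[ut]
  reg_sel <- dvec > 0 & dvec <= max_dist
  if (sum(reg_sel) < 3L) {
    stop("fewer than 3 pairs with 0 < distance <= max_dist", call. = FALSE)
  }
  if (stats::sd(dvec[reg_sel]) == 0) {
    stop("all pairwise distances identical; slope undefined", call. = FALSE)
  }
  f1_sel <- dvec <= first_class_limit
  stat_fun <- function(kmat) {
    kvec <- kmat[ut]
    b <- if (slope_on == "pairs") {
      stats::cov(kvec[reg_sel], log(dvec[reg_sel])) /
        stats::var(log(dvec[reg_sel]))
    } else {
      cls <- distance_class(dvec, class_limits)
      mids <- class_limits - diff(c(0, class_limits)) / 2
      cm <- class_means(kvec, cls, length(class_limits))
      ok <- is.finite(cm)
      stats::cov(cm[ok], log(mids[ok])) / stats::var(log(mids[ok]))
    }
    c(F1 = mean(kvec[f1_sel]), b_log = b)
  }
  obs <- stat_fun(k)
  p_f1 <- p_b <- NA_real_
  if (n_perm > 0L) {
    n <- nrow(k)
    perm <- with_seed(derive_seed(seed, 1L), {
      t(vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n)
        stat_fun(k[idx, idx])
      }, numeric(2)))
    })
    two_sided <- function(obs_v, perm_v) {
      ge <- sum(perm_v >= obs_v - 1e-12) + 1
      le <- sum(perm_v <= obs_v + 1e-12) + 1
      min(1, 2 * min(ge, le) / (n_perm + 1))
    }
    p_f1 <- two_sided(obs[["F1"]], perm[, "F1"])
    p_b <- two_sided(obs[["b_log"]], perm[, "b_log"])
  }
  structure(list(n = length(keep), F1 = obs[["F1"]], b_log = obs[["b_log"]],
                 Sp = sp_statistic(obs[["F1"]], obs[["b_log"]]),
                 p_F1 = p_f1, p_b_log = p_b,
                 n_pairs_first_class = sum(f1_sel),
                 n_pairs_regression = sum(reg_sel)),
            class = "sgs_summary")
}

#' @export
print.sgs_summary <- function(x, ...) {
  cat(sprintf("<sgs_summary> n = %d; F(1) = %.3f (p = %s); b_log = %.3f (p = %s); Sp = %.3f\n",
              x$n, x$F1, format.pval(x$p_F1), x$b_log, format.pval(x$p_b_log),
              x$Sp))
  invisible(x)
}
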