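#' Locus quality filter for dominant-marker data
#'
#' Removes loci that are monomorphic or that deviate in only a single
#' individual across the dataset: with one deviant individual a band
#' difference is indistinguishable from a scoring artefact, so such loci
#' would bias downstream parameter estimation.  Retained loci therefore have
#' at least `min_minority` individuals (default 2) in the minority state.
#'
#' The rule is applied across the pooled dataset by default, matching
#' single-batch scoring; set `scope_groups` to apply it within groups and
#' drop a locus only if it fails in every group.
#'
#' @param m a [marker_matrix()].
#' @param min_minority minimum number of individuals in the minority state
#'   for a locus to be retained.
#' @param scope_groups optional factor/character vector of length `nrow(m)`;
#'   when supplied, a locus is retained if it passes the rule in at least one
#'   group.
#' @return list with elements `matrix` (the filtered [marker_matrix()]) and
#'   `report`, a `locus_filter_report` with counts partitioning the input
#'   loci (`n_input_loci = n_monomorphic + n_single_deviant + n_retained`)
#'   and the removed locus ids.
#' @examples
#' m <- marker_matrix(cbind(mono = rep(1, 6), dev1 = c(0, 1, 1, 1, 1, 1),
#'                          ok = c(0, 0, 1, 1, 0, 1)))
#' filter_loci(m)$report
#' @export
filter_loci <- function(m, min_minority = 2L, scope_groups = NULL) {
  counts1 <- colSums(unclass(m))
  n <- nrow(m)
  minority <- pmin(counts1, n - counts1)
  if (is.null(scope_groups)) {
    monomorphic <- minority == 0L
    single_dev <- minority > 0L & minority < min_minority
  } else {
    stopifnot(length(scope_groups) == nrow(m))
    per_group <- lapply(split(seq_len(n), scope_groups), function(idx) {
      c1 <- colSums(unclass(m)[idx, , drop = FALSE])
      pmin(c1, length(idx) - c1)
    })
    best <- do.call(pmax, per_group)
    monomorphic <- minority == 0L
    single_dev <- !monomorphic & best < min_minority
  }
  keep <- !monomorphic & !single_dev
  report <- structure(list(
    n_input_loci = ncol(m),
    n_monomorphic = sum(monomorphic),
    n_single_deviant = sum(single_dev),
    n_retained = sum(keep),
    removed_locus_ids = colnames(m)[!keep]
  ), class = "locus_filter_report")
  if (!any(keep)) stop("no polymorphic loci retained", call. = FALSE)
  list(matrix = marker_matrix(unclass(m)[, keep, drop = FALSE]),
       report = report)
}

#' @export
print.locus_filter_report <- function(x, ...) {
  cat(sprintf(paste0("<locus_filter_report> %d input loci: %d monomorphic, ",
                     "%d single-deviant, %d retained (%.1f%% polymorphic)\n"),
              x$n_input_loci, x$n_monomorphic, x$n_single_deviant,
              x$n_retained, 100 * x$n_retained / x$n_input_loci))
  invisible(x)
}

#' Replicate pairs for genotyping-error estimation
#'
#' @param pairs two-column matrix or data.frame of (sample_id_a, sample_id_b)
#'   replicate duplicates.
#' @return a `replicate_pairs` object.
#' @export
replicate_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  if (nrow(pairs) < 1L) stop("at least one replicate pair required", call. = FALSE)
  ids <- as.character(pairs)
  if (anyDuplicated(ids)) {
    stop("a sample may appear in at most one replicate pair", call. = FALSE)
  }
  structure(list(a = as.character(pairs[, 1L]), b = as.character(pairs[, 2L])),
            class = "replicate_pairs")
}

#' Replicate-based genotyping error rate
#'
#' Mismatch rate between replicate profiles: total mismatching cells across
#' all pairs divided by (number of pairs times number of loci).  The marker
#' matrix passed in defines the locus set; pass the post-filter matrix for
#' the conventional estimate or the raw matrix for a pre-filter rate.
#'
#' @param m a [marker_matrix()] containing both members of every pair.
#' @param reps a [replicate_pairs()] object.
#' @return mismatch fraction in \[0, 1\].
#' @export
replicate_error_rate <- function(m, reps) {
  stopifnot(inherits(reps, "replicate_pairs"))
  all_ids <- c(reps$a, reps$b)
  missing_ids <- setdiff(all_ids, rownames(m))
  if (length(missing_ids)) {
    stop("replicate sample(s) not in matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  mism <- sum(unclass(m)[reps$a, , drop = FALSE] !=
                unclass(m)[reps$b, , drop = FALSE])
  mism / (length(reps$a) * ncol(m))
}
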