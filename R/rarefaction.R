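#' Rarefied band richness
#'
#' Expected number of distinct band states (present/absent) per locus in a
#' random draw of `g` individuals without replacement, averaged over loci.
#' For a locus with `n1` band-present individuals out of `N`, the expected
#' state count is
#' \deqn{Br = [1 - C(N-n1, g)/C(N, g)] + [1 - C(N-n0, g)/C(N, g)]}
#' with `n0 = N - n1` and `C(a, b) = 0` for `a < b`.  Values lie in
#' \[1, 2\]: a monomorphic locus always shows exactly one state.
#'
#' @param m a [marker_matrix()] for one group of individuals.
#' @param g rarefaction size, `2 <= g <= nrow(m)`.
#' @return list with `per_locus` (named vector of per-locus expectations)
#'   and `Br` (their mean).
#' @export
band_richness <- function(m, g) {
  N <- nrow(m)
  check_rarefaction_size(g, N)
  n1 <- colSums(unclass(m))
  per_locus <- (1 - hyper_miss(n1, N, g)) + (1 - hyper_miss(N - n1, N, g))
  list(per_locus = per_locus, Br = mean(per_locus))
}

check_rarefaction_size <- function(g, N) {
  if (g < 2) stop("rarefaction size g must be at least 2", call. = FALSE)
  if (g > N) {
    stop(sprintf("rarefaction size g = %d exceeds group size N = %d", g, N),
         call. = FALSE)
  }
  invisible(g)
}

#' Percentage of polymorphic loci at a frequency level, under rarefaction
#'
#' A locus counts as polymorphic when its minority-state frequency in a
#' rarefied sample of size `g` strictly exceeds `level` (the conventional
#' "5% level" with the default).  The rarefied expectation has no convenient
#' closed form for this threshold event, so it is estimated as the mean over
#' `R` seeded Monte-Carlo subsamples of `g` individuals.
#'
#' @param m a [marker_matrix()].
#' @param g rarefaction size.
#' @param level minority-frequency threshold (strict inequality).
#' @param R number of Monte-Carlo subsamples.
#' @param seed RNG seed for the subsampling.
#' @return percentage in \[0, 100\].
#' @export
plp <- function(m, g, level = 0.05, R = 1000L, seed = 1L) {
  N <- nrow(m)
  check_rarefaction_size(g, N)
  vals <- unclass(m)
  if (g == N) {
    freq <- colMeans(vals)
    minority <- pmin(freq, 1 - freq)
    return(100 * mean(minority > level))
  }
  with_seed(seed, {
    reps <- vapply(seq_len(R), function(r) {
      idx <- sample.int(N, g)
      freq <- colMeans(vals[idx, , drop = FALSE])
      minority <- pmin(freq, 1 - freq)
      mean(minority > level)
    }, numeric(1))
    100 * mean(reps)
  })
}

#' Rarefied private band richness between two paired groups
#'
#' Expected number of bands detected in a size-`g` sample from one group but
#' not in a size-`g` sample from the other (Kalinowski-style private
#' richness, band-presence state only).  Per locus the detection probability
#' in group c is `Q_c = 1 - C(N_c - n1_c, g)/C(N_c, g)`; the locus
#' contributes `Q_a (1 - Q_b)` to the first group's private richness and
#' symmetrically for the second.
#'
#' @param a,b [marker_matrix()] objects over the same locus set.
#' @param g rarefaction size, at most `min(nrow(a), nrow(b))`.
#' @return named numeric vector `c(PBr_a = ..., PBr_b = ...)`.
#' @export
private_band_richness <- function(a, b, g) {
  if (!identical(colnames(a), colnames(b))) {
    stop("the two groups must share an identical locus set", call. = FALSE)
  }
  check_rarefaction_size(g, nrow(a))
  check_rarefaction_size(g, nrow(b))
  qa <- 1 - hyper_miss(colSums(unclass(a)), nrow(a), g)
  qb <- 1 - hyper_miss(colSums(unclass(b)), nrow(b), g)
  c(PBr_a = sum(qa * (1 - qb)), PBr_b = sum(qb * (1 - qa)))
}

#' Rarefied multilocus-genotype richness and proportion of unique phenotypes
#'
#' Rows are grouped into identical multilocus band phenotypes with counts
#' `N_i`; the expected number of distinct phenotypes in a draw of `g`
#' individuals is `eMLG = sum_i [1 - C(N - N_i, g)/C(N, g)]`, and the
#' proportion of unique phenotypes is scaled as `Pu = (eMLG - 1)/(g - 1)`.
#'
#' @param m a [marker_matrix()].
#' @param g rarefaction size.
#' @return named numeric vector `c(eMLG = ..., Pu = ...)`.
#' @export
proportion_unique <- function(m, g) {
  N <- nrow(m)
  check_rarefaction_size(g, N)
  keys <- apply(unclass(m), 1L, paste, collapse = "")
  counts <- as.integer(table(keys))
  emlg <- sum(1 - hyper_miss(counts, N, g))
  c(eMLG = emlg, Pu = (emlg - 1) / (g - 1))
}
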