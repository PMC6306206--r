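#' Estimate the null-allele frequency at a dominant locus
#'
#' Dominant markers hide the heterozygote: band absence requires two copies
#' of the recessive (null) allele.  With inbreeding coefficient `F`, the
#' expected band-absence frequency is `h = q^2 (1 - F) + q F`; this solves
#' the quadratic for `q` in \[0, 1\].
#'
#' @param absence_freq observed band-absence frequency h (vectorized).
#' @param inbreeding_f assumed inbreeding coefficient F in \[0, 1).
#' @return estimated null-allele frequency q; `F = 0` reduces to `sqrt(h)`.
#' @export
null_allele_freq <- function(absence_freq, inbreeding_f = 0.5) {
  if (inbreeding_f < 0 || inbreeding_f >= 1) {
    stop("inbreeding_f must lie in [0, 1)", call. = FALSE)
  }
  if (inbreeding_f == 0) return(sqrt(absence_freq))
  a <- 1 - inbreeding_f
  (-inbreeding_f + sqrt(inbreeding_f^2 + 4 * a * absence_freq)) / (2 * a)
}

#' Pairwise kinship coefficients for dominant markers
#'
#' Moment estimator of pairwise kinship from band phenotypes under an
#' assumed inbreeding coefficient `F` (the dominant-marker analogue of
#' allele-frequency based kinship; the motivating survey used `F = 0.5`).
#' Per locus, with null-allele frequency `q` estimated by
#' [null_allele_freq()] from the band-absence frequency and `p = 1 - q`,
#' the expected covariance of the band phenotypes of two individuals with
#' kinship `theta` is, to first order in `theta`,
#' `4 p q (q + F p)^2 * theta` (derivation in the package vignette).  The
#' single-locus estimator is therefore
#' \deqn{F_ij(l) = (y_i - f_l)(y_j - f_l) / [4 p q (q + F p)^2]}
#' with `y` the 0/1 phenotype and `f_l` the sample band frequency, and the
#' multilocus estimate is the ratio of summed numerators to summed
#' denominators, i.e. loci are weighted by their information content
#' (the denominator).  With reference frequencies taken from the sample
#' itself, the mean off-diagonal kinship is close to zero by construction
#' (a small `-O(1/n)` bias remains, as for any sample-referenced kinship).
#'
#' Loci with band-absence frequency 0 or 1, or whose estimated `q` falls
#' outside \[0, 1\], carry no pairwise information and are skipped with a
#' warning.
#'
#' @param m a [marker_matrix()] of post-filter loci.
#' @param inbreeding_f assumed inbreeding coefficient in \[0, 1).
#' @return a `kinship_matrix`: symmetric n x n matrix, diagonal `NA`,
#'   with attributes `inbreeding_f` and `n_loci_used`.
#' @export
kinship_matrix <- function(m, inbreeding_f = 0.5) {
  v <- unclass(m)
  f_band <- colMeans(v)
  h <- 1 - f_band
  usable <- h > 0 & h < 1
  if (!any(usable)) stop("no polymorphic loci for kinship", call. = FALSE)
  if (any(!usable)) {
    warning(sprintf("%d monomorphic locus/loci skipped for kinship",
                    sum(!usable)), call. = FALSE)
  }
  q <- null_allele_freq(h[usable], inbreeding_f)
  bad_q <- q < 0 | q > 1
  if (any(bad_q)) {
    warning(sprintf("%d locus/loci dropped (null-allele frequency outside [0,1])",
                    sum(bad_q)), call. = FALSE)
    keep <- which(usable)[!bad_q]
    q <- q[!bad_q]
  } else {
    keep <- which(usable)
  }
  if (!length(keep)) stop("no usable loci for kinship", call. = FALSE)
  p <- 1 - q
  denom <- 4 * p * q * (q + inbreeding_f * p)^2
  centered <- sweep(v[, keep, drop = FALSE], 2L, f_band[keep])
  num <- tcrossprod(centered)               # sum_l (y_i - f)(y_j - f)
  k <- num / sum(denom)
  diag(k) <- NA_real_
  dimnames(k) <- list(rownames(m), rownames(m))
  structure(k, class = c("kinship_matrix", "matrix", "array"),
            inbreeding_f = inbreeding_f, n_loci_used = length(keep))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d individuals, %d loci, F = %.2f; mean F_ij = %.4f\n",
              nrow(x), attr(x, "n_loci_used"), attr(x, "inbreeding_f"),
              mean(x[upper.tri(x)])))
  invisible(x)
}
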