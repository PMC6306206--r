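# run code with a locally set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed (kept below 2^31) from a base seed
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% .Machine$integer.max)
}

# sample() without the scalar-first-argument surprise
sample_safe <- function(x, size = length(x), ...) {
  if (length(x) == 1L) return(rep_len(x, size))
  sample(x, size, ...)
}

rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# probability that a size-g draw without replacement from N misses all k
# marked items: C(N-k, g) / C(N, g); zero when N-k < g
hyper_miss <- function(k, N, g) {
  out <- exp(lchoose(N - k, g) - lchoose(N, g))
  out[N - k < g] <- 0
  out
}
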