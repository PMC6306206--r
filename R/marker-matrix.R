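#' Construct a binary marker matrix
#'
#' A `marker_matrix` holds dominant-marker band phenotypes: one row per
#' individual, one column per locus, entries strictly 0 (band absent) or
#' 1 (band present).  AFLP scoring yields complete binary calls, so missing
#' values are rejected rather than imputed.
#'
#' @param values numeric or integer matrix of 0/1 values.
#' @param sample_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param locus_ids character vector of unique column identifiers; defaults to
#'   `colnames(values)`.
#' @return an object of class `marker_matrix`: an integer matrix with
#'   `dimnames` set to the sample and locus identifiers.
#' @examples
#' m <- marker_matrix(rbind(s1 = c(1, 0), s2 = c(0, 1), s3 = c(1, 1)),
#'                    locus_ids = c("L1", "L2"))
#' band_frequencies(m)
#' @export
marker_matrix <- function(values, sample_ids = rownames(values),
                          locus_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- paste0("locus_", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values)) {
    stop("`sample_ids` must have one entry per row", call. = FALSE)
  }
  if (length(locus_ids) != ncol(values)) {
    stop("`locus_ids` must have one entry per column", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(sample_ids), as.character(locus_ids))
  out <- structure(values, class = c("marker_matrix", "matrix", "array"))
  validate_marker_matrix(out)
  out
}

validate_marker_matrix <- function(m) {
  if (anyNA(m)) stop("marker matrix contains missing values", call. = FALSE)
  if (!all(m == 0L | m == 1L)) {
    stop("marker matrix entries must be 0 or 1", call. = FALSE)
  }
  if (nrow(m) < 2L) stop("marker matrix needs at least 2 samples", call. = FALSE)
  if (ncol(m) < 1L) stop("marker matrix needs at least 1 locus", call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample_id: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate locus_id: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  invisible(m)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d samples x %d loci; mean band frequency %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Per-locus band (presence) frequencies
#'
#' @param m a [marker_matrix()].
#' @return named numeric vector, one value per locus, in \[0, 1\].
#' @export
band_frequencies <- function(m) {
  colMeans(unclass(m))
}

#' Subset a marker matrix by sample identifiers
#'
#' @param m a [marker_matrix()].
#' @param sample_ids character vector of row identifiers to keep, in order.
#' @return a [marker_matrix()] restricted to the requested samples.
#' @export
subset_samples <- function(m, sample_ids) {
  missing_ids <- setdiff(sample_ids, rownames(m))
  if (length(missing_ids)) {
    stop("sample ids not in marker matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  marker_matrix(unclass(m)[sample_ids, , drop = FALSE])
}

guess_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a binary marker matrix from delimited text
#'
#' Expects a header row `sample_id,<locus ids...>` followed by one row per
#' individual with strictly 0/1 cells.  Both comma- and tab-delimited files
#' are accepted (sniffed from the header).  Parse errors report the
#' offending line number.
#'
#' @param path path to a CSV/TSV file.
#' @return a [marker_matrix()] with row and column order as in the file.
#' @seealso [write_marker_matrix()]
#' @export
read_marker_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) {
    stop("marker file needs a header and at least 2 sample rows: ", path,
         call. = FALSE)
  }
  delim <- guess_delim(lines[[1L]])
  header <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("line 1: header must contain sample_id plus at least one locus id",
         call. = FALSE)
  }
  locus_ids <- trimws(header[-1L])
  n_loci <- length(locus_ids)
  rows <- vector("list", length(lines) - 1L)
  ids <- character(length(lines) - 1L)
  for (i in seq_along(rows)) {
    fields <- trimws(strsplit(lines[[i + 1L]], delim, fixed = TRUE)[[1L]])
    if (length(fields) != n_loci + 1L) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, n_loci + 1L, length(fields)), call. = FALSE)
    }
    cells <- fields[-1L]
    bad <- which(!cells %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf("line %d: non-binary cell \"%s\" at locus \"%s\"",
                   i + 1L, cells[bad[1L]], locus_ids[bad[1L]]), call. = FALSE)
    }
    ids[i] <- fields[1L]
    rows[[i]] <- as.integer(cells)
  }
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  colnames(values) <- locus_ids
  marker_matrix(values)
}

#' Write a marker matrix as delimited text
#'
#' @param m a [marker_matrix()].
#' @param path output file path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, delim = ",") {
  header <- paste(c("sample_id", colnames(m)), collapse = delim)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], unclass(m)[i, ]), collapse = delim)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
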