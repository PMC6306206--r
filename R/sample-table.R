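#' Sample metadata table
#'
#' Per-sample population, region, habitat and cohort labels plus grid
#' coordinates (metres).  Seed-bank (SB) samples may additionally carry a
#' germination-tray identifier and the grid coordinates of the two soil-core
#' cells pooled into that tray (`tray_x1`, `tray_y1`, `tray_x2`, `tray_y2`),
#' which [sb_coordinates()] uses to place them spatially.
#'
#' @param df data.frame with columns `sample_id`, `population`, `region`
#'   (`"R"`/`"T"`), `habitat` (`"meadow"`/`"woodland"`), `cohort`
#'   (`"AG"`/`"SB"`), `x`, `y`, and optionally `tray_id` and tray source-cell
#'   coordinates.  Enum fields are matched case-insensitively.
#' @return a validated data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "population", "region", "habitat", "cohort", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  df$population <- as.character(df$population)
  df$region <- match_enum(df$region, c("R", "T"), "region")
  df$habitat <- match_enum(df$habitat, c("meadow", "woodland"), "habitat")
  df$cohort <- match_enum(df$cohort, c("AG", "SB"), "cohort")
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  if (any(stats::na.omit(c(df$x, df$y)) < 0)) {
    stop("grid coordinates must be non-negative", call. = FALSE)
  }
  if (!"tray_id" %in% names(df)) df$tray_id <- NA_character_
  df$tray_id <- as.character(df$tray_id)
  df$tray_id[!nzchar(df$tray_id) | is.na(df$tray_id)] <- NA_character_
  if (any(df$cohort == "AG" & !is.na(df$tray_id))) {
    stop("aboveground (AG) samples must not carry a tray_id", call. = FALSE)
  }
  for (v in c("habitat", "region")) {
    bad <- tapply(df[[v]], df$population, function(z) length(unique(z)) > 1L)
    if (any(bad)) {
      stop(v, " is not constant within population: ",
           paste(names(bad)[bad], collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

match_enum <- function(x, levels, field) {
  x <- as.character(x)
  idx <- match(toupper(trimws(x)), toupper(levels))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop(sprintf("invalid %s value(s) %s; allowed: %s", field,
                 paste(shQuote(bad), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  levels[idx]
}

#' Read a sample metadata table from delimited text
#'
#' @param path CSV/TSV file with the columns documented in [sample_table()].
#' @return a `sample_table`.
#' @export
read_sample_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- guess_delim(first)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  sample_table(df)
}

#' Write a sample table as delimited text
#'
#' @param s a [sample_table()].
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(s, path, delim = ",") {
  utils::write.table(as.data.frame(s), path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

# align a sample table to a marker matrix: same ids, matrix row order
align_samples <- function(m, s) {
  missing_ids <- setdiff(rownames(m), s$sample_id)
  if (length(missing_ids)) {
    stop("samples missing from sample table: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  s[match(rownames(m), s$sample_id), , drop = FALSE]
}
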