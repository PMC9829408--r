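#' Construct a validated point table
#'
#' The sole required input to a hatched scatter plot: an ordered collection
#' of points, each with an id, x/y coordinates in data units, and a
#' categorical group label (cluster, cell type, frame id, ...).
#'
#' @param x,y Numeric coordinate vectors of equal length. Must be finite.
#' @param group Vector of group labels (coerced to character, whitespace
#'   trimmed). Labels are compared as exact strings; no case folding.
#' @param id Optional vector of unique point identifiers. Defaults to the
#'   0-based row index, matching common single-cell export conventions.
#' @return A `point_table`: a data.frame with columns `id`, `x`, `y`,
#'   `group`, preserving input order, with a `groups` attribute holding the
#'   group levels in order of first appearance.
#' @examples
#' pts <- point_table(x = c(0, 1, 2), y = c(0, 1, 0), group = c("a", "a", "b"))
#' nrow(pts)
#' point_groups(pts)
#' @export
point_table <- function(x, y, group, id = NULL) {
  if (length(x) == 0L) {
    stop("empty input: a point table needs at least one record", call. = FALSE)
  }
  if (length(y) != length(x) || length(group) != length(x)) {
    stop("x, y and group must have equal length", call. = FALSE)
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x))[1L]
    stop(sprintf("non-finite x coordinate at row %d", bad), call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    bad <- which(!is.finite(y))[1L]
    stop(sprintf("non-finite y coordinate at row %d", bad), call. = FALSE)
  }
  group <- trimws(as.character(group))
  if (anyNA(group) || any(group == "")) {
    stop("group labels must be non-missing, non-empty strings", call. = FALSE)
  }
  if (is.null(id)) {
    id <- as.character(seq_along(x) - 1L)
  } else {
    id <- trimws(as.character(id))
    if (anyDuplicated(id)) {
      dup <- id[duplicated(id)][1L]
      stop(sprintf("duplicate point id '%s'", dup), call. = FALSE)
    }
  }
  out <- data.frame(id = id, x = x, y = y, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- unique(group)
  class(out) <- c("point_table", "data.frame")
  out
}

#' Group levels of a point table
#'
#' @param points A `point_table`.
#' @return Character vector of group labels in order of first appearance.
#' @export
point_groups <- function(points) {
  g <- attr(points, "groups")
  if (is.null(g)) g <- unique(points$group)
  g
}

#' @export
print.point_table <- function(x, ...) {
  cat(sprintf("point_table: %d points, %d groups (%s)\n",
              nrow(x), length(point_groups(x)),
              paste(utils::head(point_groups(x), 5L), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# delimiter from extension: .csv -> comma; .tsv/.txt -> tab
.detect_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", ",")
}

#' Read a point table from a delimited text file
#'
#' Reads a CSV/TSV file with a header row and builds a validated
#' [point_table()]. The delimiter is auto-detected from the file extension
#' (`.csv` comma; `.tsv`/`.txt` tab) unless given explicitly. Rows are
#' never reordered.
#'
#' @param path Path to an existing delimited text file.
#' @param x_field,y_field Names of the numeric coordinate columns.
#' @param group_field Name of the categorical group column.
#' @param id_field Optional name of a unique-id column; when absent, ids
#'   default to the 0-based row index.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the
#'   extension.
#' @return A `point_table`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(X = 1:3, Y = 0, cluster = "c1"), f, row.names = FALSE)
#' read_point_table(f, "X", "Y", "cluster")
#' @export
read_point_table <- function(path, x_field, y_field, group_field,
                             id_field = NULL, delim = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  if (is.null(delim)) delim <- .detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop(sprintf("empty input: %s has no data rows", path), call. = FALSE)
  }
  needed <- c(x_field, y_field, group_field, id_field)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  parse_num <- function(v, field) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s': cannot parse value '%s' as a finite number at data row %d",
                   field, v[bad[1L]], bad[1L]), call. = FALSE)
    }
    out
  }
  point_table(x = parse_num(raw[[x_field]], x_field),
              y = parse_num(raw[[y_field]], y_field),
              group = raw[[group_field]],
              id = if (is.null(id_field)) NULL else raw[[id_field]])
}

#' Write a point table to a delimited text file
#'
#' Inverse of [read_point_table()]: coordinates are written at full
#' precision so that a write/read round trip reproduces the table exactly.
#'
#' @param points A `point_table`.
#' @param path Output path; extension selects the delimiter as in
#'   [read_point_table()].
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_point_table <- function(points, path, delim = NULL) {
  stopifnot(inherits(points, "point_table"))
  if (is.null(delim)) delim <- .detect_delim(path)
  df <- as.data.frame(points)
  df$x <- format(df$x, digits = 17, trim = TRUE, scientific = FALSE)
  df$y <- format(df$y, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a sparse-override id list
#'
#' One point id per line, plain text; blank lines ignored. The returned
#' ids are intended for [apply_sparse_override()].
#'
#' @param path Path to the id list file.
#' @return Character vector of ids.
#' @export
read_sparse_override <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("sparse-override file not found: %s", path), call. = FALSE)
  }
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}
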