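.pattern_names <- c("horizontal", "vertical", "positiveDiagonal",
                    "negativeDiagonal", "cross", "checkers", "blank")

.pattern_angles <- list(
  horizontal       = 0,
  vertical         = 90,
  positiveDiagonal = 45,
  negativeDiagonal = 135,
  cross            = c(0, 90),
  checkers         = c(45, 135),
  blank            = numeric(0)
)

.line_types <- c("solid", "dashed", "dotted", "dotdash", "longdash", "twodash")

#' Describe a hatch pattern
#'
#' A pattern is a set of parallel-line families. It is named (one of
#' `'horizontal'`, `'vertical'`, `'positiveDiagonal'`, `'negativeDiagonal'`,
#' `'cross'`, `'checkers'`, `'blank'`) or custom, via a numeric vector of
#' line angles in degrees (`angle = c(45, 90, 135)` gives a three-line
#' pattern). An explicit `angle` overrides the name. Per-line aesthetics
#' follow the usual line grammar: width, color, dash type, alpha.
#'
#' @param pattern Pattern name; ignored when `angle` is given.
#' @param angle Optional numeric vector of line angles in degrees, each in
#'   \[0, 180\]; 180 is the same undirected direction as 0 and is
#'   normalized to it.
#' @param lineWidth Line width in points (> 0), or `NULL` to scale with the
#'   rendered point size at resolution time.
#' @param lineColor Line color string, or `NULL` to derive from the group
#'   fill at render time (darkened fill for region hatching, white on dark
#'   fills for sparse-point glyphs).
#' @param lineType Dash style: one of `'solid'`, `'dashed'`, `'dotted'`,
#'   `'dotdash'`, `'longdash'`, `'twodash'`.
#' @param lineAlpha Line opacity in \[0, 1\]; default 1.
#' @return A `pattern_spec` list.
#' @examples
#' pattern_spec("checkers")
#' pattern_spec(angle = c(45, 90, 135), lineType = "dotted")
#' @export
pattern_spec <- function(pattern = "horizontal", angle = NULL,
                         lineWidth = NULL, lineColor = NULL,
                         lineType = "solid", lineAlpha = 1) {
  if (is.null(angle)) {
    if (!pattern %in% .pattern_names) {
      stop(sprintf("unknown pattern '%s'; valid names: %s", pattern,
                   paste(.pattern_names, collapse = ", ")), call. = FALSE)
    }
  } else {
    angle <- as.numeric(angle)
    if (any(!is.finite(angle)) || any(angle < 0 | angle > 180)) {
      stop("pattern angles must be finite and within [0, 180] degrees",
           call. = FALSE)
    }
    pattern <- "custom"
  }
  if (!is.null(lineWidth) && (!is.numeric(lineWidth) || lineWidth <= 0)) {
    stop("lineWidth must be > 0", call. = FALSE)
  }
  if (!lineType %in% .line_types) {
    stop(sprintf("unknown lineType '%s'; valid types: %s", lineType,
                 paste(.line_types, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(lineAlpha) || lineAlpha < 0 || lineAlpha > 1) {
    stop("lineAlpha must be within [0, 1]", call. = FALSE)
  }
  structure(list(pattern = pattern, angle = angle, lineWidth = lineWidth,
                 lineColor = lineColor, lineType = lineType,
                 lineAlpha = lineAlpha),
            class = "pattern_spec")
}

#' Style defaults used when resolving a pattern
#'
#' @param point_size Rendered marker diameter in points; the default line
#'   width is 0.15 times this diameter.
#' @param lineWidth,lineColor,lineType,lineAlpha Fallback aesthetics; a
#'   `NULL` `lineColor` is resolved against the group fill at render time.
#' @return A list of default line aesthetics.
#' @export
pattern_defaults <- function(point_size = 3, lineWidth = 0.15 * point_size,
                             lineColor = NULL, lineType = "solid",
                             lineAlpha = 1) {
  list(lineWidth = lineWidth, lineColor = lineColor, lineType = lineType,
       lineAlpha = lineAlpha)
}

#' Resolve a pattern description into concrete line families
#'
#' Maps a named pattern to its angle set (horizontal 0; vertical 90;
#' positiveDiagonal 45; negativeDiagonal 135; cross 0 and 90; checkers 45
#' and 135; blank none), applies any custom angle list, normalizes 180 to
#' 0, and fills each family's aesthetics from the spec, else from
#' `defaults`. Families are ordered by ascending angle.
#'
#' @param spec A [pattern_spec()] (or an already-resolved `hatch_spec`,
#'   returned unchanged).
#' @param defaults Style fallbacks from [pattern_defaults()].
#' @return A `hatch_spec`: a data.frame with one row per line family and
#'   columns `angle`, `width`, `color` (possibly `NA` until render),
#'   `linetype`, `alpha`. Zero rows encode the blank pattern.
#' @examples
#' resolve_pattern(pattern_spec("cross"))
#' nrow(resolve_pattern(pattern_spec("blank")))
#' @export
resolve_pattern <- function(spec, defaults = pattern_defaults()) {
  if (inherits(spec, "hatch_spec")) return(spec)
  stopifnot(inherits(spec, "pattern_spec"))
  angles <- if (!is.null(spec$angle)) spec$angle else .pattern_angles[[spec$pattern]]
  angles <- sort(unique(angles %% 180))
  width <- spec$lineWidth %||% defaults$lineWidth
  color <- spec$lineColor %||% defaults$lineColor %||% NA_character_
  fam <- data.frame(angle = angles,
                    width = rep(width, length(angles)),
                    color = rep(color, length(angles)),
                    linetype = rep(spec$lineType, length(angles)),
                    alpha = rep(spec$lineAlpha, length(angles)),
                    stringsAsFactors = FALSE)
  structure(fam, pattern = spec$pattern,
            class = c("hatch_spec", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The default pattern cycle
#'
#' Seven patterns in fixed cycling order: six line patterns (horizontal,
#' vertical, the two diagonals, cross, checkers) plus blank, the
#' color-only mode. Combined with the 40-color default palette this gives
#' 280 distinct (color, pattern) codes.
#'
#' @return An ordered list of 7 `pattern_spec` objects.
#' @examples
#' vapply(default_patterns(), function(p) p$pattern, "")
#' @export
default_patterns <- function() {
  lapply(.pattern_names, pattern_spec)
}
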