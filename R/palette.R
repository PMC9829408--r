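# 40 colorblind-friendly colors following the dittoSeq convention:
# 8 Okabe-Ito-derived base colors, then 40%-darker, 40%-lighter, and
# further shade variants, interleaved so nearby indices stay distinct.
.default_colors <- c(
  "#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
  "#D55E00", "#CC79A7", "#666666", "#AD7700", "#1C91D4",
  "#007756", "#D5C711", "#005685", "#A04700", "#B14380",
  "#4D4D4D", "#FFBE2D", "#80C7EF", "#00F6B3", "#F4EB71",
  "#06A5FF", "#FF8320", "#D99BBD", "#8C8C8C", "#FFCB57",
  "#9AD2F2", "#2CFFC6", "#F6EF8E", "#38B7FF", "#FF9B4D",
  "#E0AFCA", "#A3A3A3", "#8A5F00", "#1674A9", "#005F45",
  "#AA9F0D", "#00446B", "#803800", "#8D3666", "#3D3D3D"
)

#' The default 40-color CVD-friendly palette
#'
#' Forty high-contrast colors safe for common color-vision deficiencies,
#' following the dittoSeq colorblind palette convention (Okabe-Ito base
#' hues plus lightness variants). Stable across runs.
#'
#' @return Character vector of 40 distinct `"#RRGGBB"` strings.
#' @examples
#' length(default_palette())
#' @export
default_palette <- function() .default_colors

.validate_palette <- function(palette) {
  if (!is.character(palette) || length(palette) < 1L) {
    stop("palette must be a non-empty character vector", call. = FALSE)
  }
  ok <- grepl("^#[0-9A-Fa-f]{6}$", palette)
  if (any(!ok)) {
    stop(sprintf("invalid palette color(s): %s",
                 paste(palette[!ok], collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(toupper(palette))) {
    stop("palette colors must be pairwise distinct", call. = FALSE)
  }
  toupper(palette)
}

#' Assign each group a (fill color, pattern) pair
#'
#' The redundant-coding contract: group n (0-based, in the given order)
#' receives color `n mod |palette|` and pattern `floor(n / |palette|) mod
#' |patterns|`, so colors are exhausted before patterns advance and the
#' first `|palette| * |patterns|` groups receive pairwise-distinct pairs
#' (280 under the defaults). Assignments are deterministic and stable:
#' appending a group never changes earlier groups' pairs.
#'
#' @param groups Character vector of distinct group labels, in display
#'   order.
#' @param palette Character vector of distinct `"#RRGGBB"` fill colors.
#' @param patterns Ordered list of [pattern_spec()] objects to cycle
#'   through.
#' @return An `aesthetic_map`: a data.frame with columns `group`, `color`,
#'   `pattern` (name) and a list-attribute `patterns` holding each group's
#'   `pattern_spec`.
#' @examples
#' am <- assign_aesthetics(c("tumor", "stroma", "immune"))
#' am$color
#' @export
assign_aesthetics <- function(groups, palette = default_palette(),
                              patterns = default_patterns()) {
  groups <- as.character(groups)
  if (length(groups) < 1L) stop("need at least one group", call. = FALSE)
  if (anyDuplicated(groups)) {
    stop("group labels must be distinct", call. = FALSE)
  }
  palette <- .validate_palette(palette)
  if (length(patterns) < 1L) stop("need at least one pattern", call. = FALSE)
  capacity <- length(palette) * length(patterns)
  if (length(groups) > capacity) {
    stop(sprintf(paste0("too many groups (%d) for %d colors x %d patterns = ",
                        "%d distinct (color, pattern) combinations"),
                 length(groups), length(palette), length(patterns), capacity),
         call. = FALSE)
  }
  n <- seq_along(groups) - 1L
  ci <- n %% length(palette) + 1L
  pi <- (n %/% length(palette)) %% length(patterns) + 1L
  specs <- patterns[pi]
  out <- data.frame(group = groups, color = palette[ci],
                    pattern = vapply(specs, function(p) p$pattern, ""),
                    stringsAsFactors = FALSE)
  attr(out, "patterns") <- specs
  class(out) <- c("aesthetic_map", "data.frame")
  out
}

#' Look up one group's aesthetics
#'
#' @param aesthetics An `aesthetic_map` from [assign_aesthetics()].
#' @param group A group label present in the map.
#' @return List with elements `color` (fill) and `pattern`
#'   (`pattern_spec`).
#' @export
group_aesthetic <- function(aesthetics, group) {
  i <- match(group, aesthetics$group)
  if (is.na(i)) {
    stop(sprintf("group '%s' is not present in the aesthetic map", group),
         call. = FALSE)
  }
  list(color = aesthetics$color[i], pattern = attr(aesthetics, "patterns")[[i]])
}

# shift a hex color toward black by fraction f
.darken <- function(hex, f = 0.4) {
  m <- grDevices::col2rgb(hex) * (1 - f)
  grDevices::rgb(m[1L, ], m[2L, ], m[3L, ], maxColorValue = 255)
}

# relative luminance (sRGB, linear light)
.luminance <- function(hex) {
  v <- grDevices::col2rgb(hex) / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  0.2126 * lin[1L, ] + 0.7152 * lin[2L, ] + 0.0722 * lin[3L, ]
}
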