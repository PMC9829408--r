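.cvd_types <- c("deuteranomaly", "protanomaly", "tritanomaly", "monochromacy")

#' Severity-interpolated CVD transfer matrix
#'
#' Returns the 3x3 linear-light RGB matrix simulating a color-vision
#' deficiency at the given severity. Anomalous trichromacies
#' (deuteranomaly: green-weak; protanomaly: red-weak; tritanomaly:
#' blue-yellow) use the published Machado matrix family; monochromacy
#' interpolates toward the Rec. 709 luminance projection (every output
#' channel the luma), i.e. grayscale vision at severity 1. Severity 0 is
#' always the identity, and rows sum to 1, so grays are fixed points.
#'
#' @param deficiency One of `"deuteranomaly"`, `"protanomaly"`,
#'   `"tritanomaly"`, `"monochromacy"`.
#' @param severity Number in \[0, 1\].
#' @return A 3x3 numeric matrix.
#' @export
cvd_transform_matrix <- function(deficiency = .cvd_types, severity = 1) {
  deficiency <- match.arg(deficiency)
  if (!is.numeric(severity) || length(severity) != 1L ||
      is.na(severity) || severity < 0 || severity > 1) {
    stop("severity must be a single number within [0, 1]", call. = FALSE)
  }
  if (deficiency == "monochromacy") {
    luma <- c(0.2126, 0.7152, 0.0722)
    proj <- matrix(rep(luma, each = 3L), nrow = 3L)
    return((1 - severity) * diag(3L) + severity * proj)
  }
  tab <- switch(deficiency,
                deuteranomaly = .deutan_matrices,
                protanomaly = .protan_matrices,
                tritanomaly = .tritan_matrices)
  pos <- severity * 10
  lo <- floor(pos); hi <- ceiling(pos); alpha <- pos - lo
  (1 - alpha) * tab[[lo + 1L]] + alpha * tab[[hi + 1L]]
}

.hex_to_linear <- function(hex) {
  v <- grDevices::col2rgb(hex) / 255
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

.linear_to_hex <- function(lin) {
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  v <- round(255 * v)
  sprintf("#%02X%02X%02X", v[1L, ], v[2L, ], v[3L, ])
}

#' Simulate how a color appears under a color-vision deficiency
#'
#' Converts each color to linear-light RGB, applies the severity-
#' interpolated deficiency matrix, clamps to gamut, and re-encodes as
#' sRGB hex. Vectorized over colors.
#'
#' @param color Character vector of colors (any form `col2rgb` accepts).
#' @param deficiency Deficiency type; see [cvd_transform_matrix()].
#' @param severity Number in \[0, 1\]; 0 returns the input unchanged.
#' @return Character vector of `"#RRGGBB"` strings.
#' @examples
#' simulate_cvd("#E69F00", "deuteranomaly", 1)
#' simulate_cvd("#E69F00", "monochromacy", 1)
#' @export
simulate_cvd <- function(color, deficiency = .cvd_types, severity = 1) {
  m <- cvd_transform_matrix(deficiency, severity)
  .linear_to_hex(m %*% .hex_to_linear(color))
}

#' Minimum pairwise perceptual separation of a palette under CVD
#'
#' Applies [simulate_cvd()] to every color and returns the minimum
#' CIEDE2000 color difference over all pairs — a scalar summary of how
#' separable the palette remains for that deficiency. Zero means two
#' colors become indistinguishable.
#'
#' @param colors Character vector of at least 2 colors.
#' @param deficiency,severity Passed to [simulate_cvd()].
#' @return Single non-negative number (CIEDE2000 units).
#' @examples
#' palette_separation(default_palette(), "deuteranomaly", 1)
#' @export
palette_separation <- function(colors, deficiency = .cvd_types,
                               severity = 1) {
  if (length(colors) < 2L) {
    stop("palette_separation needs at least 2 colors", call. = FALSE)
  }
  sim <- simulate_cvd(colors, deficiency, severity)
  rgbm <- t(grDevices::col2rgb(sim))
  d <- farver::compare_colour(rgbm, rgbm, from_space = "rgb",
                              method = "cie2000")
  min(d[upper.tri(d)])
}

#' Recolor a rendered figure as seen under a CVD
#'
#' Applies [simulate_cvd()] to every style color in the figure — marker
#' fills, hatch and glyph strokes, legend swatches — while leaving all
#' geometry (segment counts, endpoints, angles, widths) untouched. This
#' is the redundant-coding audit: the pattern channel must survive any
#' color collapse.
#'
#' @param fig A `hatch_figure`.
#' @param deficiency,severity Passed to [simulate_cvd()].
#' @return A new `hatch_figure` with transformed colors only.
#' @export
simulate_figure_cvd <- function(fig, deficiency = .cvd_types, severity = 1) {
  stopifnot(inherits(fig, "hatch_figure"))
  recol <- function(v) if (length(v)) simulate_cvd(v, deficiency, severity) else v
  fig$markers$color <- recol(fig$markers$color)
  fig$region_segments$color <- recol(fig$region_segments$color)
  fig$glyph_segments$color <- recol(fig$glyph_segments$color)
  if (!is.null(fig$legend)) {
    fig$legend$entries$color <- recol(fig$legend$entries$color)
    fig$legend$samples$color <- recol(fig$legend$samples$color)
  }
  fig$aesthetics$color <- recol(fig$aesthetics$color)
  fig
}
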