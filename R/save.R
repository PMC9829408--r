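.num <- function(v) {
  # fixed-format numbers so output is byte-stable across platforms
  s <- sprintf("%.3f", v)
  sub("^-0\\.000$", "0.000", s)
}

.svg_dash <- function(linetype, width) {
  code <- .lty_mm[[linetype]]
  if (is.na(code)) return("")
  units <- as.integer(strsplit(code, "")[[1L]])
  sprintf(' stroke-dasharray="%s"',
          paste(.num(units * width), collapse = ","))
}

# one drawable element per marker / segment; y axis flipped to SVG space
.write_svg <- function(fig, path) {
  H <- fig$height
  fy <- function(y) H - y
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) {
    writeLines(sprintf(...), con, sep = "\n", useBytes = TRUE)
  }
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    .num(fig$width), .num(H), .num(fig$width), .num(H))
  w('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
    .num(fig$width), .num(H))
  m <- fig$markers
  w('<g class="markers">')
  if (nrow(m) > 0L) {
    writeLines(sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                       .num(m$x), .num(fy(m$y)),
                       .num(fig$canvas$point_size / 2), m$color),
               con, useBytes = TRUE)
  }
  w('</g>')
  seg_lines <- function(s) {
    if (nrow(s) == 0L) return(character(0))
    dash <- vapply(seq_len(nrow(s)),
                   function(k) .svg_dash(s$linetype[k], s$width[k]), "")
    alpha <- ifelse(s$alpha < 1,
                    sprintf(' stroke-opacity="%s"', .num(s$alpha)), "")
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s%s/>',
            .num(s$x1), .num(fy(s$y1)), .num(s$x2), .num(fy(s$y2)),
            s$color, .num(s$width), dash, alpha)
  }
  w('<g class="region-hatch">')
  writeLines(seg_lines(fig$region_segments), con, useBytes = TRUE)
  w('</g>')
  w('<g class="glyphs">')
  writeLines(seg_lines(fig$glyph_segments), con, useBytes = TRUE)
  w('</g>')
  if (!is.null(fig$legend)) {
    w('<g class="legend">')
    e <- fig$legend$entries
    writeLines(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#000000" stroke-width="0.300"/>',
                       .num(e$x), .num(fy(e$y + e$size)), .num(e$size),
                       .num(e$size), e$color),
               con, useBytes = TRUE)
    writeLines(seg_lines(fig$legend$samples), con, useBytes = TRUE)
    writeLines(sprintf('<text x="%s" y="%s" font-size="9" font-family="sans-serif">%s</text>',
                       .num(e$x + e$size + 4), .num(fy(e$y + 2)),
                       vapply(e$group, .xml_escape, "")),
               con, useBytes = TRUE)
    w('</g>')
  }
  w('</svg>')
  invisible(path)
}

.xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# blank out PDF creation/modification timestamps in place, preserving
# byte offsets so the file stays valid
.strip_pdf_dates <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  close_paren <- as.raw(41L)
  for (key in c("/CreationDate (D:", "/ModDate (D:")) {
    hits <- grepRaw(key, raw, fixed = TRUE, all = TRUE)
    for (start in hits) {
      pos <- start + nchar(key)
      while (pos <= length(raw) && raw[pos] != close_paren) {
        raw[pos] <- as.raw(48L)   # '0'
        pos <- pos + 1L
      }
    }
  }
  writeBin(raw, path)
  invisible(path)
}

#' Write a figure to disk
#'
#' SVG output uses the package's own deterministic writer: one `<circle>`
#' per marker and one `<line>` per hatch/glyph segment, no timestamps, so
#' saving the same figure twice yields byte-identical files and tests can
#' count drawable elements. PNG and PDF are rasterized/typeset through
#' ggplot2; PDF timestamps are blanked after writing.
#'
#' @param fig A `hatch_figure` from [render_plot()].
#' @param path Output file path.
#' @param format One of `"svg"`, `"png"`, `"pdf"`; default inferred from
#'   the path extension.
#' @param dpi Raster resolution for PNG; default 300.
#' @return `path`, invisibly.
#' @examples
#' pts <- make_embedding_fixture(n_groups = 2, n_dense_per_group = 150,
#'                               n_sparse_per_group = 5, seed = 3)
#' f <- tempfile(fileext = ".svg")
#' save_figure(render_plot(pts), f)
#' file.exists(f)
#' @export
save_figure <- function(fig, path, format = NULL, dpi = 300) {
  stopifnot(inherits(fig, "hatch_figure"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("svg", "png", "pdf")) {
    stop(sprintf("unsupported format '%s'; supported formats: svg, png, pdf",
                 format), call. = FALSE)
  }
  if (format == "svg") {
    return(.write_svg(fig, path))
  }
  p <- as_ggplot(fig)
  w_in <- fig$width / 72; h_in <- fig$height / 72
  if (format == "png") {
    grDevices::png(path, width = w_in, height = h_in, units = "in",
                   res = dpi)
    print(p)
    grDevices::dev.off()
  } else {
    grDevices::pdf(path, width = w_in, height = h_in)
    print(p)
    grDevices::dev.off()
    .strip_pdf_dates(path)
  }
  invisible(path)
}
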