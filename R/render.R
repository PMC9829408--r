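.styled_empty <- function() {
  data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
             y2 = numeric(0), width = numeric(0), color = character(0),
             linetype = character(0), alpha = numeric(0), group = character(0),
             stringsAsFactors = FALSE)
}

# fill NA family colors: darkened fill for region hatching, white on dark
# fills for glyph chords
.resolve_hatch_colors <- function(hatch, fill, context = c("region", "glyph")) {
  context <- match.arg(context)
  na <- is.na(hatch$color)
  if (any(na)) {
    hatch$color[na] <- if (context == "glyph" && .luminance(fill) < 0.5) {
      "#FFFFFF"
    } else {
      .darken(fill, 0.4)
    }
  }
  hatch
}

#' Render a hatched scatter figure
#'
#' Composes the full figure from its parts: a colored base scatter, coarse
#' hatching clipped to each group's dense-cluster regions, a per-marker
#' pattern glyph on every sparse point, and a legend whose swatches carry
#' both the fill color and a sample of the pattern. The result is a pure
#' function of its inputs — no randomness — so identical inputs give
#' identical figures.
#'
#' Layer order is fixed: base markers, then region hatching, then sparse
#' glyphs (glyphs always on top). Groups are drawn in input order;
#' overlapping groups simply overdraw.
#'
#' @param points A `point_table`.
#' @param labels Optional `sparsity_labels`; default runs
#'   [classify_sparse_dense()] with `config` on `canvas`.
#' @param aesthetics Optional `aesthetic_map`; default assigns the default
#'   palette and pattern cycle in group order. Must cover every group.
#' @param canvas A [canvas_spec()].
#' @param config A [grid_config()] used when `labels` is `NULL`, and to
#'   grid dense points into region masks.
#' @param spacing Perpendicular hatch-line spacing for region hatching,
#'   display points; default 4 times the pattern line width.
#' @param legend Draw a legend? Default `TRUE`.
#' @return A `hatch_figure` with introspectable components: `markers`,
#'   `region_segments`, `glyph_segments`, `legend`, `width`, `height`.
#' @examples
#' pts <- make_embedding_fixture(n_groups = 3, n_dense_per_group = 200,
#'                               n_sparse_per_group = 15, seed = 7)
#' fig <- render_plot(pts)
#' segment_counts(fig)
#' @export
render_plot <- function(points, labels = NULL, aesthetics = NULL,
                        canvas = canvas_spec(), config = grid_config(),
                        spacing = NULL, legend = TRUE) {
  stopifnot(inherits(points, "point_table"), inherits(canvas, "canvas_spec"))
  groups <- point_groups(points)
  if (is.null(aesthetics)) aesthetics <- assign_aesthetics(groups)
  missing_groups <- setdiff(groups, aesthetics$group)
  if (length(missing_groups) > 0L) {
    stop(sprintf("group(s) present in points but absent from aesthetics: %s",
                 paste(missing_groups, collapse = ", ")), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- classify_sparse_dense(points, config = config, canvas = canvas)
  }
  if (!identical(labels$id, points$id)) {
    stop("labels must cover exactly the points of the table, in order",
         call. = FALSE)
  }
  disp <- .to_display(points, canvas)
  r <- canvas$point_size / 2
  bin <- .resolve_bin_size(config, canvas)
  dp <- points
  dp$x <- disp$x; dp$y <- disp$y

  # base markers, grouped in group order (draw order across groups)
  ord <- order(match(points$group, groups))
  markers <- data.frame(x = disp$x[ord], y = disp$y[ord],
                        group = points$group[ord],
                        color = aesthetics$color[match(points$group[ord],
                                                       aesthetics$group)],
                        stringsAsFactors = FALSE)

  region <- list(); glyph <- list()
  grid <- build_occupancy_grid(dp, bin_size = bin)
  for (g in groups) {
    aes_g <- group_aesthetic(aesthetics, g)
    hatch <- resolve_pattern(aes_g$pattern,
                             pattern_defaults(point_size = canvas$point_size))
    sel <- points$group == g
    dense_sel <- sel & labels$label == "dense"
    if (nrow(hatch) > 0L && any(dense_sel)) {
      hreg <- .resolve_hatch_colors(hatch, aes_g$color, "region")
      cells <- unique(grid$point_cell[dense_sel, c("i", "j"), drop = FALSE])
      mask <- region_mask(cells, origin = grid$origin, bin_size = bin,
                          group = g)
      for (f in seq_len(nrow(hreg))) {
        sp <- spacing %||% (4 * hreg$width[f])
        seg <- hatch_segments(mask, hreg$angle[f], spacing = sp)
        if (nrow(seg) > 0L) {
          seg$width <- hreg$width[f]; seg$color <- hreg$color[f]
          seg$linetype <- hreg$linetype[f]; seg$alpha <- hreg$alpha[f]
          seg$group <- g
          region[[length(region) + 1L]] <- seg
        }
      }
    }
    sparse_idx <- which(sel & labels$label == "sparse")
    if (nrow(hatch) > 0L && length(sparse_idx) > 0L) {
      hgly <- .resolve_hatch_colors(hatch, aes_g$color, "glyph")
      for (p in sparse_idx) {
        seg <- glyph_segments(c(disp$x[p], disp$y[p]), marker_radius = r,
                              hatch = hgly)
        if (nrow(seg) > 0L) {
          seg$angle <- NULL
          seg$group <- g
          glyph[[length(glyph) + 1L]] <- seg
        }
      }
    }
  }
  region <- if (length(region)) do.call(rbind, region) else .styled_empty()
  glyph <- if (length(glyph)) do.call(rbind, glyph) else .styled_empty()
  rownames(region) <- NULL; rownames(glyph) <- NULL

  leg <- if (legend) .build_legend(aesthetics, canvas) else NULL
  width_total <- canvas$width + if (legend) leg$panel_width else 0

  structure(list(canvas = canvas, width = width_total,
                 height = canvas$height, markers = markers,
                 region_segments = region, glyph_segments = glyph,
                 legend = leg, aesthetics = aesthetics, labels = labels),
            class = "hatch_figure")
}

# legend: 12x12 pt swatches, each hatched with a 2-line-per-family sample
.build_legend <- function(aesthetics, canvas) {
  sw <- 12; row_h <- 18; col_w <- 110; pad <- 10
  usable <- canvas$height - 2 * canvas$margin
  per_col <- max(1L, floor(usable / row_h))
  n <- nrow(aesthetics)
  n_cols <- ceiling(n / per_col)
  entries <- list(); samples <- list()
  for (k in seq_len(n)) {
    col_k <- (k - 1L) %/% per_col
    row_k <- (k - 1L) %% per_col
    x0 <- canvas$width + pad + col_k * col_w
    y0 <- canvas$height - canvas$margin - row_k * row_h - sw
    entries[[k]] <- data.frame(group = aesthetics$group[k],
                               color = aesthetics$color[k],
                               pattern = aesthetics$pattern[k],
                               x = x0, y = y0, size = sw,
                               stringsAsFactors = FALSE)
    hatch <- resolve_pattern(attr(aesthetics, "patterns")[[k]],
                             pattern_defaults(point_size = canvas$point_size))
    if (nrow(hatch) > 0L) {
      hatch <- .resolve_hatch_colors(hatch, aesthetics$color[k], "region")
      m <- region_mask(data.frame(i = 0L, j = 0L), origin = c(x0, y0),
                       bin_size = sw, group = aesthetics$group[k])
      for (f in seq_len(nrow(hatch))) {
        seg <- hatch_segments(m, hatch$angle[f], spacing = sw / 2,
                              phase = sw / 4)
        if (nrow(seg) > 0L) {
          seg$width <- hatch$width[f]; seg$color <- hatch$color[f]
          seg$linetype <- hatch$linetype[f]; seg$alpha <- hatch$alpha[f]
          seg$group <- aesthetics$group[k]
          samples[[length(samples) + 1L]] <- seg
        }
      }
    }
  }
  list(entries = do.call(rbind, entries),
       samples = if (length(samples)) do.call(rbind, samples) else .styled_empty(),
       panel_width = pad + n_cols * col_w)
}

#' Per-layer drawable counts of a figure
#'
#' @param fig A `hatch_figure`.
#' @return List with counts of markers, region hatch segments, glyph
#'   segments, and legend entries.
#' @export
segment_counts <- function(fig) {
  stopifnot(inherits(fig, "hatch_figure"))
  list(markers = nrow(fig$markers),
       region = nrow(fig$region_segments),
       glyph = nrow(fig$glyph_segments),
       legend_entries = if (is.null(fig$legend)) 0L else nrow(fig$legend$entries))
}

#' @export
print.hatch_figure <- function(x, ...) {
  sc <- segment_counts(x)
  cat(sprintf(paste0("hatch_figure: %d markers in %d groups; %d region hatch ",
                     "segments, %d glyph segments, %d legend entries; canvas ",
                     "%g x %g pt\n"),
              sc$markers, length(unique(x$markers$group)), sc$region,
              sc$glyph, sc$legend_entries, x$width, x$height))
  invisible(x)
}

.lty_mm <- c(solid = NA, dashed = "44", dotted = "13", dotdash = "1343",
             longdash = "73", twodash = "2262")

#' Convert a figure to a ggplot object
#'
#' Builds a ggplot2 scatter in display coordinates with the hatch and
#' glyph segments as annotation layers and a standard color legend. Used
#' for raster (png/pdf) export; the native SVG writer preserves exact
#' per-segment structure instead.
#'
#' @param fig A `hatch_figure`.
#' @return A ggplot object.
#' @export
as_ggplot <- function(fig) {
  stopifnot(inherits(fig, "hatch_figure"))
  pt_mm <- 0.352778                       # 1 typographic point in mm
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = fig$markers,
      ggplot2::aes(x = x, y = y, colour = group),
      size = fig$canvas$point_size * pt_mm / 0.75 / 2,
      show.legend = !is.null(fig$legend)) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(fig$aesthetics$color, fig$aesthetics$group),
      name = NULL) +
    ggplot2::coord_fixed(xlim = c(0, fig$canvas$width),
                         ylim = c(0, fig$height), expand = FALSE) +
    ggplot2::theme_void()
  add_segs <- function(p, segs) {
    if (nrow(segs) == 0L) return(p)
    for (lt in unique(segs$linetype)) {
      s <- segs[segs$linetype == lt, , drop = FALSE]
      p <- p + ggplot2::annotate("segment", x = s$x1, y = s$y1,
                                 xend = s$x2, yend = s$y2,
                                 colour = s$color, alpha = s$alpha,
                                 linewidth = s$width * pt_mm / 0.75,
                                 linetype = lt)
    }
    p
  }
  p <- add_segs(p, fig$region_segments)
  add_segs(p, fig$glyph_segments)
}
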