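#' Construct a region mask from grid cells
#'
#' A region mask is a set of occupied square grid cells (the union of
#' which is the dense region to hatch) together with the grid geometry.
#'
#' @param cells data.frame with integer columns `i`, `j` (cell indices).
#' @param origin Numeric length-2 grid origin.
#' @param bin_size Cell side (> 0), display units.
#' @param group Group label the mask belongs to (informational).
#' @param component Component index (informational).
#' @return A `region_mask`.
#' @export
region_mask <- function(cells, origin, bin_size, group = "", component = NA) {
  stopifnot(is.data.frame(cells), all(c("i", "j") %in% names(cells)),
            bin_size > 0, length(origin) == 2L)
  cells <- unique(cells[, c("i", "j"), drop = FALSE])
  cells <- cells[order(cells$j, cells$i), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(group = group, component = component, cells = cells,
                 origin = as.numeric(origin), bin_size = bin_size),
            class = "region_mask")
}

#' Split an occupancy grid into 8-connected region masks
#'
#' Labels the (optionally restricted) occupied cells of each group with
#' 8-connected component ids and returns one `region_mask` per component,
#' ordered by group, then row-major by each component's minimal cell.
#'
#' @param grid An `occupancy_grid` from [build_occupancy_grid()].
#' @param cells Optional data.frame with columns `group`, `i`, `j`
#'   restricting which cells participate (e.g. dense cells only); `NULL`
#'   uses every occupied cell.
#' @return List of `region_mask` objects (empty when there are no cells).
#' @examples
#' pts <- point_table(x = c(0, 1, 10), y = c(0, 0, 0), group = rep("a", 3))
#' g <- build_occupancy_grid(pts, bin_size = 1)
#' length(connected_components(g))   # two separated blobs
#' @export
connected_components <- function(grid, cells = NULL) {
  stopifnot(inherits(grid, "occupancy_grid"))
  use <- grid$cells[, c("group", "i", "j"), drop = FALSE]
  if (!is.null(cells)) {
    key_all <- paste(use$group, use$i, use$j)
    key_sel <- paste(cells$group, cells$i, cells$j)
    use <- use[key_all %in% key_sel, , drop = FALSE]
  }
  out <- list()
  for (g in grid$groups) {
    gc <- use[use$group == g, , drop = FALSE]
    if (nrow(gc) == 0L) next
    comp <- .cell_components(gc)
    for (k in sort(unique(comp))) {
      out[[length(out) + 1L]] <- region_mask(gc[comp == k, , drop = FALSE],
                                             origin = grid$origin,
                                             bin_size = grid$bin_size,
                                             group = g, component = k)
    }
  }
  out
}

# clip the infinite line p(t) = p0 + t*d to the axis-aligned box; returns
# c(tmin, tmax) or NULL when the line misses the box
.clip_line_box <- function(p0, d, box, eps = 1e-12) {
  tmin <- -Inf; tmax <- Inf
  for (axis in 1:2) {
    lo <- box[2L * axis - 1L]; hi <- box[2L * axis]
    if (abs(d[axis]) < eps) {
      if (p0[axis] < lo - eps || p0[axis] > hi + eps) return(NULL)
    } else {
      t1 <- (lo - p0[axis]) / d[axis]
      t2 <- (hi - p0[axis]) / d[axis]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin > tmax) NULL else c(tmin, tmax)
}

# merge sorted-by-start intervals that overlap or touch within tol
.merge_intervals <- function(starts, ends, tol) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] <= me + tol) {
      me <- max(me, ends[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

#' Clip a family of parallel hatch lines to a region mask
#'
#' Generates the family of parallel lines at `angle_deg` whose
#' perpendicular offsets are `phase + n * spacing` from the low edge of the
#' mask's bounding box, intersects each with the union of the mask's
#' occupied cells, and returns each maximal run inside the mask as one
#' segment. Angles are measured in display coordinates, so the drawn
#' pattern angle is independent of data-unit aspect ratio.
#'
#' @param mask A `region_mask`.
#' @param angle_deg Line angle in degrees, in \[0, 180\] (0 horizontal, 90
#'   vertical); 180 is normalized to 0.
#' @param spacing Perpendicular distance between consecutive lines (> 0),
#'   display units.
#' @param phase Offset of the first line from the mask's low edge along the
#'   family normal; defaults to `spacing / 2` so even a one-cell mask
#'   receives a line.
#' @return data.frame with columns `x1`, `y1`, `x2`, `y2` (display units),
#'   zero rows for an empty mask.
#' @examples
#' m <- region_mask(data.frame(i = 0L, j = 0L), origin = c(0, 0), bin_size = 1)
#' hatch_segments(m, angle_deg = 0, spacing = 0.5, phase = 0.25)
#' @export
hatch_segments <- function(mask, angle_deg, spacing, phase = spacing / 2) {
  stopifnot(inherits(mask, "region_mask"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("spacing must be a single number > 0", call. = FALSE)
  }
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0))
  n_cells <- nrow(mask$cells)
  if (n_cells == 0L) return(empty)
  b <- mask$bin_size
  theta <- (angle_deg %% 180) * pi / 180
  d <- c(cos(theta), sin(theta))
  nrm <- c(-sin(theta), cos(theta))
  # cell boxes in display coordinates
  x0 <- mask$origin[1L] + mask$cells$i * b
  y0 <- mask$origin[2L] + mask$cells$j * b
  # perpendicular-offset range of the mask union
  cx <- c(x0, x0 + b, x0, x0 + b)
  cy <- c(y0, y0, y0 + b, y0 + b)
  cvals <- cx * nrm[1L] + cy * nrm[2L]
  cmin <- min(cvals); cmax <- max(cvals)
  if (cmin + phase > cmax) return(empty)
  offsets <- seq(cmin + phase, cmax, by = spacing)
  cell_c <- (x0 + b / 2) * nrm[1L] + (y0 + b / 2) * nrm[2L]
  reach <- b * (abs(nrm[1L]) + abs(nrm[2L])) / 2 + 1e-9
  segs <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    cc <- offsets[k]
    p0 <- cc * nrm
    near <- which(abs(cell_c - cc) <= reach)
    if (length(near) == 0L) next
    ts <- matrix(numeric(0), ncol = 2L)
    for (ci in near) {
      tt <- .clip_line_box(p0, d, c(x0[ci], x0[ci] + b, y0[ci], y0[ci] + b))
      if (!is.null(tt) && tt[2L] > tt[1L]) ts <- rbind(ts, tt)
    }
    if (nrow(ts) == 0L) next
    runs <- .merge_intervals(ts[, 1L], ts[, 2L], tol = 1e-9 * b)
    segs[[k]] <- data.frame(x1 = p0[1L] + runs[, 1L] * d[1L],
                            y1 = p0[2L] + runs[, 1L] * d[2L],
                            x2 = p0[1L] + runs[, 2L] * d[1L],
                            y2 = p0[2L] + runs[, 2L] * d[2L])
  }
  out <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Pattern glyph for a single sparse point
#'
#' Draws the pattern's line families as chords of the marker disk: for
#' each family, chords at the family's angle with perpendicular offsets
#' `m * glyph_spacing` (m = 0, +/-1, ...), centered so one chord passes
#' through the marker center. Every chord endpoint lies on the marker
#' circle.
#'
#' @param center Numeric length-2 marker center, display units.
#' @param marker_radius Marker radius (> 0), display units.
#' @param hatch A resolved `hatch_spec` (zero rows = blank, no chords).
#' @param glyph_spacing Perpendicular chord spacing; defaults to
#'   `marker_radius` (at most 3 chords per family).
#' @return data.frame with columns `x1`, `y1`, `x2`, `y2`, `angle`,
#'   `width`, `color`, `linetype`, `alpha`; one row per chord.
#' @export
glyph_segments <- function(center, marker_radius, hatch,
                           glyph_spacing = marker_radius) {
  if (!is.numeric(marker_radius) || marker_radius <= 0) {
    stop("marker_radius must be > 0", call. = FALSE)
  }
  if (!is.numeric(glyph_spacing) || glyph_spacing <= 0) {
    stop("glyph_spacing must be > 0", call. = FALSE)
  }
  hatch <- resolve_pattern(hatch)
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), angle = numeric(0), width = numeric(0),
                      color = character(0), linetype = character(0),
                      alpha = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hatch) == 0L) return(empty)
  r <- marker_radius
  mmax <- ceiling(r / glyph_spacing)
  offs <- glyph_spacing * seq(-mmax, mmax)
  offs <- offs[abs(offs) < r * (1 - 1e-9)]
  segs <- lapply(seq_len(nrow(hatch)), function(f) {
    theta <- (hatch$angle[f] %% 180) * pi / 180
    d <- c(cos(theta), sin(theta))
    nrm <- c(-sin(theta), cos(theta))
    hl <- sqrt(r^2 - offs^2)
    data.frame(x1 = center[1L] + offs * nrm[1L] - hl * d[1L],
               y1 = center[2L] + offs * nrm[2L] - hl * d[2L],
               x2 = center[1L] + offs * nrm[1L] + hl * d[1L],
               y2 = center[2L] + offs * nrm[2L] + hl * d[2L],
               angle = hatch$angle[f], width = hatch$width[f],
               color = hatch$color[f], linetype = hatch$linetype[f],
               alpha = hatch$alpha[f], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
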