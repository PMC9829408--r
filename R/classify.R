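#' Canvas specification
#'
#' Rendering geometry in typographic points. The sparse/dense detector and
#' all hatching operate in these display coordinates, after the data-to-
#' canvas transform, so pattern angles and spacings describe what the
#' reader sees rather than data units.
#'
#' @param width,height Canvas size in points.
#' @param margin Inner margin (points) around the plotting region.
#' @param point_size Rendered marker diameter in points. Drives the default
#'   classification bin size and default pattern line width.
#' @param equal_aspect If `TRUE`, x and y share one scale (recommended for
#'   in-situ spatial plots); otherwise each axis fills the plot region.
#' @return A `canvas_spec` list.
#' @export
canvas_spec <- function(width = 480, height = 480, margin = 24,
                        point_size = 3, equal_aspect = FALSE) {
  stopifnot(width > 2 * margin, height > 2 * margin, point_size > 0)
  structure(list(width = width, height = height, margin = margin,
                 point_size = point_size, equal_aspect = equal_aspect),
            class = "canvas_spec")
}

# affine data -> display transform for a data bounding box
.display_transform <- function(bbox, canvas) {
  dx <- bbox[2L] - bbox[1L]
  dy <- bbox[4L] - bbox[3L]
  if (dx <= 0) { bbox[1L] <- bbox[1L] - 0.5; dx <- 1 }
  if (dy <= 0) { bbox[3L] <- bbox[3L] - 0.5; dy <- 1 }
  w <- canvas$width - 2 * canvas$margin
  h <- canvas$height - 2 * canvas$margin
  sx <- w / dx
  sy <- h / dy
  if (canvas$equal_aspect) sx <- sy <- min(sx, sy)
  # center the used region inside the plot area
  ox <- canvas$margin + (w - sx * dx) / 2 - sx * bbox[1L]
  oy <- canvas$margin + (h - sy * dy) / 2 - sy * bbox[3L]
  list(sx = sx, sy = sy, ox = ox, oy = oy)
}

.data_bbox <- function(points) {
  c(min(points$x), max(points$x), min(points$y), max(points$y))
}

.to_display <- function(points, canvas) {
  tr <- .display_transform(.data_bbox(points), canvas)
  list(x = tr$ox + tr$sx * points$x, y = tr$oy + tr$sy * points$y, tr = tr)
}

#' Detector configuration for sparse/dense classification
#'
#' Points are binned on a square grid; a point counts as dense when its
#' cell's 3x3 same-group neighborhood holds at least `density_threshold`
#' points and that cell belongs to an 8-connected component of such cells
#' with at least `min_cluster_cells` cells. Everything else is sparse.
#'
#' @param bin_size Grid cell side in display points. Default `NULL` derives
#'   it as `bin_factor * point_size` from the canvas at classification
#'   time, so the grid tracks the rendered marker size.
#' @param bin_factor Multiplier on the rendered point diameter used when
#'   `bin_size` is `NULL`.
#' @param density_threshold Minimum same-group point count in a cell's 3x3
#'   neighborhood (k >= 1).
#' @param min_cluster_cells Smallest 8-connected cell component kept as a
#'   dense region (>= 1).
#' @return A `grid_config` list.
#' @export
grid_config <- function(bin_size = NULL, bin_factor = 1.5,
                        density_threshold = 4L, min_cluster_cells = 2L) {
  if (!is.null(bin_size) && bin_size <= 0) {
    stop("bin_size must be > 0", call. = FALSE)
  }
  if (bin_factor <= 0) stop("bin_factor must be > 0", call. = FALSE)
  density_threshold <- as.integer(density_threshold)
  min_cluster_cells <- as.integer(min_cluster_cells)
  if (density_threshold < 1L) stop("density_threshold must be >= 1", call. = FALSE)
  if (min_cluster_cells < 1L) stop("min_cluster_cells must be >= 1", call. = FALSE)
  structure(list(bin_size = bin_size, bin_factor = bin_factor,
                 density_threshold = density_threshold,
                 min_cluster_cells = min_cluster_cells),
            class = "grid_config")
}

.resolve_bin_size <- function(config, canvas) {
  if (!is.null(config$bin_size)) config$bin_size
  else config$bin_factor * canvas$point_size
}

# half-open cells [x0 + i*b, x0 + (i+1)*b)
.cell_index <- function(v, origin, bin_size) {
  as.integer(floor((v - origin) / bin_size + 1e-9))
}

.cell_key <- function(i, j) paste(i, j, sep = ",")

#' Build a per-group occupancy grid
#'
#' Bins points on a square grid with half-open cells (left/bottom edge
#' inclusive), so every point maps to exactly one cell and per-group cell
#' counts sum to the group's point count.
#'
#' @param points A `point_table` (coordinates are used as given; callers
#'   working in display space pass display coordinates).
#' @param bin_size Cell side, in the same units as the coordinates; > 0.
#' @param origin Numeric length-2 grid origin `(x0, y0)`; defaults to the
#'   lower-left corner of the point bounding box.
#' @return An `occupancy_grid`: occupied cells with per-group counts, plus
#'   the grid geometry.
#' @export
build_occupancy_grid <- function(points, bin_size, origin = NULL) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("bin_size must be a single number > 0", call. = FALSE)
  }
  if (is.null(origin)) origin <- c(min(points$x), min(points$y))
  i <- .cell_index(points$x, origin[1L], bin_size)
  j <- .cell_index(points$y, origin[2L], bin_size)
  tab <- stats::aggregate(list(count = rep(1L, nrow(points))),
                          by = list(group = points$group, i = i, j = j),
                          FUN = sum)
  tab <- tab[order(match(tab$group, point_groups(points)), tab$j, tab$i), ,
             drop = FALSE]
  rownames(tab) <- NULL
  structure(list(cells = tab, origin = origin, bin_size = bin_size,
                 groups = point_groups(points),
                 point_cell = data.frame(i = i, j = j,
                                         group = points$group,
                                         stringsAsFactors = FALSE)),
            class = "occupancy_grid")
}

# 3x3 neighborhood point count for each occupied cell, within one group
.neighborhood_counts <- function(cells) {
  key <- .cell_key(cells$i, cells$j)
  counts <- stats::setNames(cells$count, key)
  total <- numeric(nrow(cells))
  for (di in -1:1) {
    for (dj in -1:1) {
      nb <- counts[.cell_key(cells$i + di, cells$j + dj)]
      nb[is.na(nb)] <- 0
      total <- total + nb
    }
  }
  total
}

# 8-connected components over a set of cells; returns integer membership
# renumbered so component ids follow row-major (min j, then min i) order
.cell_components <- function(cells) {
  n <- nrow(cells)
  if (n == 0L) return(integer(0))
  key <- .cell_key(cells$i, cells$j)
  idx <- stats::setNames(seq_len(n), key)
  from <- integer(0); to <- integer(0)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    nb <- idx[.cell_key(cells$i + o[1L], cells$j + o[2L])]
    hit <- !is.na(nb)
    from <- c(from, which(hit)); to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # deterministic ordering: by minimal (j, i) cell of each component
  ord <- order(cells$j, cells$i)
  first <- ord[!duplicated(memb[ord])]
  rank <- stats::setNames(seq_along(first), memb[first])
  as.integer(rank[as.character(memb)])
}

#' Classify each point as dense-cluster member or sparse singleton
#'
#' Runs the grid-based detector independently for every group: points are
#' binned in display space, cells whose 3x3 same-group neighborhood holds
#' at least `density_threshold` points are dense candidates, and candidates
#' are kept only when their 8-connected component spans at least
#' `min_cluster_cells` cells. Points in kept cells are labeled `dense`;
#' all others `sparse`.
#'
#' @param points A `point_table`.
#' @param config A [grid_config()].
#' @param canvas A [canvas_spec()] giving the display transform under which
#'   density is judged.
#' @return A `sparsity_labels` data.frame with columns `id`, `group`,
#'   `label` (`"dense"`/`"sparse"`), one row per point in input order, with
#'   attribute `provenance = "detector"`.
#' @examples
#' pts <- make_embedding_fixture(n_groups = 2, n_dense_per_group = 300,
#'                               n_sparse_per_group = 10, seed = 1)
#' table(classify_sparse_dense(pts)$label)
#' @export
classify_sparse_dense <- function(points, config = grid_config(),
                                  canvas = canvas_spec()) {
  stopifnot(inherits(points, "point_table"), inherits(config, "grid_config"))
  disp <- .to_display(points, canvas)
  bin <- .resolve_bin_size(config, canvas)
  dp <- points
  dp$x <- disp$x; dp$y <- disp$y
  grid <- build_occupancy_grid(dp, bin_size = bin)
  label <- rep("sparse", nrow(points))
  for (g in point_groups(points)) {
    sel <- grid$cells$group == g
    cells <- grid$cells[sel, , drop = FALSE]
    dense_cell <- .neighborhood_counts(cells) >= config$density_threshold
    dc <- cells[dense_cell, , drop = FALSE]
    if (nrow(dc) > 0L) {
      comp <- .cell_components(dc)
      keep <- comp %in% which(tabulate(comp) >= config$min_cluster_cells)
      dc <- dc[keep, , drop = FALSE]
      if (nrow(dc) > 0L) {
        pmask <- points$group == g
        pkey <- .cell_key(grid$point_cell$i[pmask], grid$point_cell$j[pmask])
        label[which(pmask)[pkey %in% .cell_key(dc$i, dc$j)]] <- "dense"
      }
    }
  }
  structure(data.frame(id = points$id, group = points$group, label = label,
                       stringsAsFactors = FALSE),
            provenance = "detector",
            class = c("sparsity_labels", "data.frame"))
}

#' Bypass the detector with an explicit sparse-point list
#'
#' The listed points are labeled sparse and every other point dense; the
#' in-built detector is not consulted.
#'
#' @param points A `point_table`.
#' @param override Character vector of point ids to treat as sparse (may be
#'   empty). Every id must exist in `points`.
#' @return A `sparsity_labels` data.frame with
#'   attribute `provenance = "override"`.
#' @export
apply_sparse_override <- function(points, override) {
  stopifnot(inherits(points, "point_table"))
  override <- trimws(as.character(override))
  unknown <- setdiff(override, points$id)
  if (length(unknown) > 0L) {
    stop(sprintf("sparse-override id(s) not present in point table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  label <- ifelse(points$id %in% override, "sparse", "dense")
  structure(data.frame(id = points$id, group = points$group, label = label,
                       stringsAsFactors = FALSE),
            provenance = "override",
            class = c("sparsity_labels", "data.frame"))
}
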