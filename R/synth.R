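# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic embedding-like point mixture
#'
#' Emulates the structure of a UMAP/tSNE embedding of clustered
#' single-cell data: each group is a compact isotropic Gaussian blob
#' (its dense cluster) surrounded by a diffuse annular halo of sparse
#' points. Blob centers are placed deterministically at equal angles on a
#' circle, so the fixture depends only on the seed and the stated
#' parameters. The planted dense/sparse assignment of every point is
#' returned in the `planted` attribute for label-recovery experiments.
#'
#' @param n_groups Number of groups (>= 1).
#' @param n_dense_per_group Gaussian blob points per group (>= 0).
#' @param n_sparse_per_group Halo points per group (>= 0).
#' @param blob_sd Blob standard deviation (data units).
#' @param halo_radius Outer radius of the sparse halo annulus; the inner
#'   radius is half of it. The default blob/halo scale separation is 20.
#' @param center_radius Radius of the circle on which blob centers sit.
#' @param seed Integer seed; the same seed always reproduces the same
#'   table, and the caller's RNG state is left untouched.
#' @return A `point_table` with attribute `planted` (character vector,
#'   `"dense"`/`"sparse"`, one per point).
#' @examples
#' pts <- make_embedding_fixture(n_groups = 4, n_dense_per_group = 100,
#'                               n_sparse_per_group = 10, seed = 1)
#' table(pts$group, attr(pts, "planted"))
#' @export
make_embedding_fixture <- function(n_groups = 4, n_dense_per_group = 2400,
                                   n_sparse_per_group = 100, blob_sd = 1,
                                   halo_radius = 20, center_radius = 20,
                                   seed = 1) {
  n_groups <- as.integer(n_groups)
  n_dense_per_group <- as.integer(n_dense_per_group)
  n_sparse_per_group <- as.integer(n_sparse_per_group)
  if (n_groups < 1L) stop("n_groups must be >= 1", call. = FALSE)
  if (n_dense_per_group < 0L || n_sparse_per_group < 0L) {
    stop("point counts must be >= 0", call. = FALSE)
  }
  if (n_dense_per_group + n_sparse_per_group == 0L) {
    stop("at least one point per group is required", call. = FALSE)
  }
  if (blob_sd <= 0 || halo_radius <= 0) {
    stop("blob_sd and halo_radius must be > 0", call. = FALSE)
  }
  .with_seed(seed, {
    xs <- list(); ys <- list(); gs <- list(); planted <- list()
    for (g in seq_len(n_groups)) {
      ang <- 2 * pi * (g - 1) / n_groups
      cx <- center_radius * cos(ang)
      cy <- center_radius * sin(ang)
      bx <- cx + stats::rnorm(n_dense_per_group, 0, blob_sd)
      by <- cy + stats::rnorm(n_dense_per_group, 0, blob_sd)
      # uniform by area over the annulus [halo_radius/2, halo_radius]
      rr <- sqrt(stats::runif(n_sparse_per_group, (halo_radius / 2)^2,
                              halo_radius^2))
      ra <- stats::runif(n_sparse_per_group, 0, 2 * pi)
      xs[[g]] <- c(bx, cx + rr * cos(ra))
      ys[[g]] <- c(by, cy + rr * sin(ra))
      gs[[g]] <- rep(sprintf("group%d", g),
                     n_dense_per_group + n_sparse_per_group)
      planted[[g]] <- c(rep("dense", n_dense_per_group),
                        rep("sparse", n_sparse_per_group))
    }
    pts <- point_table(x = unlist(xs), y = unlist(ys), group = unlist(gs))
    attr(pts, "planted") <- unlist(planted)
    pts
  })
}

#' Synthetic tiled spatial point table
#'
#' Emulates an in-situ microscopy acquisition: a rectangular grid of
#' frames, each frame one group, with points uniform inside its tile.
#' With a 2 x 41 grid this reproduces the many-group regime of 82 frames.
#'
#' @param n_frames_x,n_frames_y Frame grid dimensions (>= 1).
#' @param cells_per_frame Points per frame (>= 1).
#' @param frame_size Tile side length in data units.
#' @param seed Integer seed; deterministic as in
#'   [make_embedding_fixture()].
#' @return A `point_table` with one group per frame (labels
#'   `frame001`, ... row-major) and attribute `frame_bounds`, a data.frame
#'   of each frame's tile rectangle.
#' @examples
#' pts <- make_spatial_fixture(n_frames_x = 2, n_frames_y = 3,
#'                             cells_per_frame = 10, seed = 1)
#' length(point_groups(pts))
#' @export
make_spatial_fixture <- function(n_frames_x = 2, n_frames_y = 41,
                                 cells_per_frame = 50, frame_size = 100,
                                 seed = 1) {
  n_frames_x <- as.integer(n_frames_x)
  n_frames_y <- as.integer(n_frames_y)
  cells_per_frame <- as.integer(cells_per_frame)
  if (n_frames_x < 1L || n_frames_y < 1L) {
    stop("frame grid dimensions must be >= 1", call. = FALSE)
  }
  if (cells_per_frame < 1L) stop("cells_per_frame must be >= 1", call. = FALSE)
  if (frame_size <= 0) stop("frame_size must be > 0", call. = FALSE)
  .with_seed(seed, {
    n_frames <- n_frames_x * n_frames_y
    fx <- rep(seq_len(n_frames_x), times = n_frames_y)
    fy <- rep(seq_len(n_frames_y), each = n_frames_x)
    lab <- sprintf("frame%03d", seq_len(n_frames))
    xs <- numeric(0); ys <- numeric(0)
    for (f in seq_len(n_frames)) {
      xs <- c(xs, stats::runif(cells_per_frame, (fx[f] - 1) * frame_size,
                               fx[f] * frame_size))
      ys <- c(ys, stats::runif(cells_per_frame, (fy[f] - 1) * frame_size,
                               fy[f] * frame_size))
    }
    pts <- point_table(x = xs, y = ys,
                       group = rep(lab, each = cells_per_frame))
    attr(pts, "frame_bounds") <- data.frame(
      group = lab,
      xmin = (fx - 1) * frame_size, xmax = fx * frame_size,
      ymin = (fy - 1) * frame_size, ymax = fy * frame_size,
      stringsAsFactors = FALSE)
    pts
  })
}
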