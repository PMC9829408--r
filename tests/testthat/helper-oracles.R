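# Independent brute-force oracles. These deliberately re-derive the
# contracts from first principles (O(n^2) neighborhood scans, explicit
# flood fill, dense sampling) and share no code with the package
# internals they check.

# data -> display mapping, written out directly (equal_aspect = FALSE)
oracle_display <- function(points, canvas) {
  dx <- max(points$x) - min(points$x); if (dx <= 0) dx <- 1
  dy <- max(points$y) - min(points$y); if (dy <= 0) dy <- 1
  list(x = canvas$margin + (points$x - min(points$x)) *
         (canvas$width - 2 * canvas$margin) / dx,
       y = canvas$margin + (points$y - min(points$y)) *
         (canvas$height - 2 * canvas$margin) / dy)
}

# per-point dense/sparse labels by exhaustive neighborhood count and
# iterative flood fill over threshold-passing cells
oracle_classify <- function(points, config, canvas) {
  d <- oracle_display(points, canvas)
  bin <- if (!is.null(config$bin_size)) config$bin_size else
    config$bin_factor * canvas$point_size
  ci <- floor((d$x - min(d$x)) / bin + 1e-9)
  cj <- floor((d$y - min(d$y)) / bin + 1e-9)
  label <- rep("sparse", nrow(points))
  for (g in unique(points$group)) {
    idx <- which(points$group == g)
    cells <- unique(data.frame(i = ci[idx], j = cj[idx]))
    # 3x3 neighborhood point count per occupied cell
    nb <- vapply(seq_len(nrow(cells)), function(r) {
      sum(abs(ci[idx] - cells$i[r]) <= 1 & abs(cj[idx] - cells$j[r]) <= 1)
    }, 0)
    pass <- cells[nb >= config$density_threshold, , drop = FALSE]
    if (nrow(pass) == 0L) next
    # flood fill, 8-connectivity
    comp <- rep(NA_integer_, nrow(pass))
    nxt <- 1L
    for (s in seq_len(nrow(pass))) {
      if (!is.na(comp[s])) next
      stack <- s
      comp[s] <- nxt
      while (length(stack) > 0L) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        adj <- which(is.na(comp) &
                       abs(pass$i - pass$i[cur]) <= 1 &
                       abs(pass$j - pass$j[cur]) <= 1)
        comp[adj] <- nxt
        stack <- c(stack, adj)
      }
      nxt <- nxt + 1L
    }
    keep <- pass[comp %in% which(tabulate(comp) >= config$min_cluster_cells), ,
                 drop = FALSE]
    if (nrow(keep) == 0L) next
    in_keep <- paste(ci[idx], cj[idx]) %in% paste(keep$i, keep$j)
    label[idx[in_keep]] <- "dense"
  }
  label
}

# hatched length of one line (angle, perpendicular offset c) inside the
# mask's cell union, by midpoint sampling at step `delta`
oracle_line_length <- function(mask, angle_deg, c_off, delta) {
  b <- mask$bin_size
  theta <- (angle_deg %% 180) * pi / 180
  d <- c(cos(theta), sin(theta))
  nrm <- c(-sin(theta), cos(theta))
  x0 <- mask$origin[1] + mask$cells$i * b
  y0 <- mask$origin[2] + mask$cells$j * b
  bb <- c(min(x0), max(x0) + b, min(y0), max(y0) + b)
  tcand <- c(bb[1] * d[1] + bb[3] * d[2], bb[1] * d[1] + bb[4] * d[2],
             bb[2] * d[1] + bb[3] * d[2], bb[2] * d[1] + bb[4] * d[2])
  tmin <- min(tcand) - b; tmax <- max(tcand) + b
  ts <- seq(tmin + delta / 2, tmax, by = delta)
  px <- c_off * nrm[1] + ts * d[1]
  py <- c_off * nrm[2] + ts * d[2]
  ki <- floor((px - mask$origin[1]) / b)
  kj <- floor((py - mask$origin[2]) / b)
  occ <- (mask$cells$i + 1000) * 100000 + (mask$cells$j + 1000)
  hit <- ((ki + 1000) * 100000 + (kj + 1000)) %in% occ
  sum(hit) * delta
}

# perpendicular-offset anchor of a mask (low edge along the family normal)
oracle_cmin <- function(mask, angle_deg) {
  b <- mask$bin_size
  theta <- (angle_deg %% 180) * pi / 180
  nrm <- c(-sin(theta), cos(theta))
  x0 <- mask$origin[1] + mask$cells$i * b
  y0 <- mask$origin[2] + mask$cells$j * b
  cx <- c(x0, x0 + b, x0, x0 + b)
  cy <- c(y0, y0, y0 + b, y0 + b)
  min(cx * nrm[1] + cy * nrm[2])
}

# random cell subset of an n x n grid
random_mask <- function(n = 8, bin_size = 10, p = 0.45) {
  cells <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  cells <- cells[stats::runif(nrow(cells)) < p, , drop = FALSE]
  if (nrow(cells) == 0L) cells <- data.frame(i = 0L, j = 0L)
  region_mask(cells, origin = c(0, 0), bin_size = bin_size)
}

# random multi-group point configuration confined to <= 20x20 grid cells
random_config <- function() {
  n_groups <- sample(1:3, 1)
  pts <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    n_clumps <- sample(0:2, 1)
    xs <- ys <- numeric(0)
    for (k in seq_len(n_clumps)) {
      cx <- stats::runif(1, 20, 80); cy <- stats::runif(1, 20, 80)
      m <- sample(5:25, 1)
      xs <- c(xs, stats::rnorm(m, cx, 4)); ys <- c(ys, stats::rnorm(m, cy, 4))
    }
    m <- sample(5:20, 1)
    xs <- c(xs, stats::runif(m, 0, 100)); ys <- c(ys, stats::runif(m, 0, 100))
    data.frame(x = xs, y = ys, group = sprintf("g%d", g))
  }))
  point_table(pts$x, pts$y, pts$group)
}

random_grid_config <- function() {
  grid_config(bin_size = 22, density_threshold = sample(1:6, 1),
              min_cluster_cells = sample(1:3, 1))
}
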