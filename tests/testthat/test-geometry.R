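test_that("component labeling separates blobs and joins diagonal touches", {
  # two blobs two empty cells apart
  pts <- point_table(c(0.5, 1.5, 5.5, 6.5), c(0.5, 0.5, 0.5, 0.5),
                     rep("a", 4))
  g <- build_occupancy_grid(pts, bin_size = 1)
  expect_length(connected_components(g), 2L)

  # restricting to no cells gives an empty list
  expect_length(connected_components(g, cells = data.frame(
    group = character(0), i = integer(0), j = integer(0))), 0L)

  # L-shape with a diagonal join is one component under 8-connectivity
  lpts <- point_table(c(0.5, 0.5, 0.5, 1.5, 2.5), c(2.5, 1.5, 0.5, 0.5, 1.5),
                      rep("a", 5))
  lg <- build_occupancy_grid(lpts, bin_size = 1)
  expect_length(connected_components(lg), 1L)
})

test_that("components come out in deterministic row-major order", {
  pts <- point_table(c(9.5, 0.5, 5.5), c(9.5, 0.5, 0.5), rep("a", 3))
  g <- build_occupancy_grid(pts, bin_size = 1)
  comps <- connected_components(g)
  firsts <- t(vapply(comps, function(m) unlist(m$cells[1L, ]), c(i = 0L, j = 0L)))
  expect_equal(order(firsts[, "j"], firsts[, "i"]), seq_len(nrow(firsts)))
})

test_that("hatch lines clip to a unit cell exactly as expected", {
  m <- region_mask(data.frame(i = 0L, j = 0L), origin = c(0, 0), bin_size = 1)
  seg <- hatch_segments(m, angle_deg = 0, spacing = 0.5, phase = 0.25)
  expect_equal(nrow(seg), 2L)
  lens <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  expect_equal(lens, c(1, 1))
  expect_equal(sort(seg$y1), c(0.25, 0.75))

  empty <- region_mask(data.frame(i = integer(0), j = integer(0)),
                       origin = c(0, 0), bin_size = 1)
  expect_equal(nrow(hatch_segments(empty, 45, 1)), 0L)
  expect_error(hatch_segments(m, 0, spacing = 0), "spacing")
})

test_that("a square mask is symmetric between horizontal and vertical", {
  cells <- expand.grid(i = 0:3, j = 0:3)
  m <- region_mask(cells, origin = c(0, 0), bin_size = 2)
  h <- hatch_segments(m, 0, spacing = 1.3, phase = 0.4)
  v <- hatch_segments(m, 90, spacing = 1.3, phase = 0.4)
  expect_equal(nrow(h), nrow(v))
  expect_equal(sum(sqrt((h$x2 - h$x1)^2 + (h$y2 - h$y1)^2)),
               sum(sqrt((v$x2 - v$x1)^2 + (v$y2 - v$y1)^2)))
})

test_that("emitted segments have the requested angle and stay inside the mask", {
  withr::local_seed(8)
  for (rep in 1:8) {
    m <- random_mask(n = 6, bin_size = runif(1, 5, 20))
    ang <- runif(1, 0, 180)
    seg <- hatch_segments(m, ang, spacing = m$bin_size / 3)
    if (nrow(seg) == 0L) next
    got <- (atan2(seg$y2 - seg$y1, seg$x2 - seg$x1) * 180 / pi) %% 180
    expect_true(all(pmin(abs(got - ang %% 180),
                         180 - abs(got - ang %% 180)) < 1e-6))
    # midpoints lie in an occupied cell
    mx <- (seg$x1 + seg$x2) / 2; my <- (seg$y1 + seg$y2) / 2
    ki <- floor((mx - m$origin[1]) / m$bin_size)
    kj <- floor((my - m$origin[2]) / m$bin_size)
    expect_true(all(paste(ki, kj) %in% paste(m$cells$i, m$cells$j)))
  }
})

test_that("hatched length per line matches the dense-sampling oracle", {
  withr::local_seed(13)
  for (rep in 1:5) {
    m <- random_mask(n = 6, bin_size = 10)
    ang <- runif(1, 0, 180)
    spacing <- runif(1, 3, 8)
    phase <- runif(1, 0.1, spacing - 0.1)
    seg <- hatch_segments(m, ang, spacing, phase)
    theta <- (ang %% 180) * pi / 180
    nrm <- c(-sin(theta), cos(theta))
    cmin <- oracle_cmin(m, ang)
    delta <- m$bin_size / 2000
    if (nrow(seg) > 0L) {
      cvals <- seg$x1 * nrm[1] + seg$y1 * nrm[2]
      midx <- round((cvals - cmin - phase) / spacing)
      lens <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
      for (mi in unique(midx)) {
        impl <- sum(lens[midx == mi])
        orc <- oracle_line_length(m, ang, cmin + phase + mi * spacing, delta)
        expect_lt(abs(impl - orc), max(0.01 * orc, 50 * delta))
      }
    }
  }
})

test_that("for a convex mask, total length x spacing approximates the area", {
  cells <- expand.grid(i = 0:4, j = 0:6)
  m <- region_mask(cells, origin = c(0, 0), bin_size = 3)
  area <- nrow(cells) * 9
  for (ang in c(0, 30, 45, 90, 120)) {
    seg <- hatch_segments(m, ang, spacing = 0.8)
    total <- sum(sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2))
    expect_lt(abs(total * 0.8 - area) / area, 0.1)
  }
})

test_that("glyph chords follow the pattern and end on the marker circle", {
  blank <- resolve_pattern(pattern_spec("blank"))
  expect_equal(nrow(glyph_segments(c(0, 0), 2, blank)), 0L)

  horiz <- resolve_pattern(pattern_spec("horizontal"),
                           pattern_defaults(point_size = 4))
  one <- glyph_segments(c(1, 2), marker_radius = 2, horiz,
                        glyph_spacing = 5)  # spacing > diameter: one chord
  expect_equal(nrow(one), 1L)
  expect_equal(sqrt((one$x2 - one$x1)^2 + (one$y2 - one$y1)^2), 4)
  expect_equal((one$y1 + one$y2) / 2, 2)    # passes through the center

  cross <- resolve_pattern(pattern_spec("cross"),
                           pattern_defaults(point_size = 4))
  two <- glyph_segments(c(1, 2), marker_radius = 2, cross, glyph_spacing = 5)
  expect_equal(nrow(two), 2L * nrow(one))

  dense_chords <- glyph_segments(c(0, 0), marker_radius = 2, horiz,
                                 glyph_spacing = 0.6)
  r1 <- sqrt(dense_chords$x1^2 + dense_chords$y1^2)
  r2 <- sqrt(dense_chords$x2^2 + dense_chords$y2^2)
  expect_true(all(abs(c(r1, r2) - 2) < 1e-9))
  expect_error(glyph_segments(c(0, 0), 0, horiz), "marker_radius")
})
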