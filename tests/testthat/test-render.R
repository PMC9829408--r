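make_small_points <- function(seed = 42) {
  make_embedding_fixture(n_groups = 2, n_dense_per_group = 200,
                         n_sparse_per_group = 10, seed = seed)
}

test_that("blank patterns degenerate to a plain colored scatter", {
  pts <- make_small_points()
  blanks <- assign_aesthetics(point_groups(pts),
                              patterns = list(pattern_spec("blank")))
  fig <- render_plot(pts, aesthetics = blanks)
  sc <- segment_counts(fig)
  expect_equal(sc$region, 0L)
  expect_equal(sc$glyph, 0L)
  expect_equal(sc$markers, nrow(pts))
  expect_equal(nrow(fig$legend$samples), 0L)
})

test_that("an all-sparse group draws the closed-form number of glyph chords", {
  pts <- point_table(runif(25, 0, 10), runif(25, 0, 10), rep("a", 25))
  labels <- apply_sparse_override(pts, pts$id)   # force all sparse
  cross <- assign_aesthetics("a", patterns = list(pattern_spec("cross")))
  fig <- render_plot(pts, labels = labels, aesthetics = cross)
  # default glyph spacing = marker radius: one chord per family per marker
  expect_equal(segment_counts(fig)$region, 0L)
  expect_equal(segment_counts(fig)$glyph, 25L * 2L * 1L)
})

test_that("rendering is a pure function of its inputs", {
  pts <- make_small_points()
  f1 <- render_plot(pts)
  f2 <- render_plot(pts)
  expect_identical(f1$markers, f2$markers)
  expect_identical(f1$region_segments, f2$region_segments)
  expect_identical(f1$glyph_segments, f2$glyph_segments)
  expect_identical(f1$legend, f2$legend)
})

test_that("a group missing from the aesthetics is a mapping error", {
  pts <- make_small_points()
  am <- assign_aesthetics(point_groups(pts)[1L])
  expect_error(render_plot(pts, aesthetics = am), "absent from aesthetics")
})

test_that("every group gets one legend entry carrying color and pattern", {
  pts <- make_small_points()
  fig <- render_plot(pts)
  e <- fig$legend$entries
  expect_equal(e$group, point_groups(pts))
  expect_equal(e$color, fig$aesthetics$color)
  for (g in point_groups(pts)) {
    expect_gte(sum(fig$legend$samples$group == g), 1L)
  }
})

test_that("hatching scales with the canvas; glyphs track the marker", {
  # doubling the canvas (and the grid/spacing that are defined in display
  # units) doubles every region-hatch segment; glyphs, which are tied to
  # the fixed marker size, keep their chord counts and lengths
  pts <- make_small_points()
  labels <- classify_sparse_dense(pts, grid_config(bin_size = 6),
                                  canvas = canvas_spec())
  small <- render_plot(pts, labels = labels, canvas = canvas_spec(),
                       config = grid_config(bin_size = 6), spacing = 2)
  big <- render_plot(pts, labels = labels,
                     canvas = canvas_spec(width = 960, height = 960,
                                          margin = 48),
                     config = grid_config(bin_size = 12), spacing = 4)
  expect_equal(nrow(big$region_segments), nrow(small$region_segments))
  len <- function(s) sqrt((s$x2 - s$x1)^2 + (s$y2 - s$y1)^2)
  expect_equal(len(big$region_segments), 2 * len(small$region_segments))
  # per-marker glyph structure is unchanged by canvas size
  expect_equal(nrow(big$glyph_segments), nrow(small$glyph_segments))
  expect_equal(len(big$glyph_segments), len(small$glyph_segments))
})

test_that("SVG output has one drawable element per figure element", {
  pts <- make_small_points()
  fig <- render_plot(pts)
  f <- withr::local_tempfile(fileext = ".svg")
  save_figure(fig, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  circles <- xml2::xml_find_all(doc, "//d1:circle", ns)
  lines <- xml2::xml_find_all(doc, "//d1:line", ns)
  rects <- xml2::xml_find_all(doc, "//d1:g[@class='legend']/d1:rect", ns)
  sc <- segment_counts(fig)
  expect_length(circles, sc$markers)
  expect_length(lines, sc$region + sc$glyph + nrow(fig$legend$samples))
  expect_length(rects, sc$legend_entries)
  # layer order: markers before region hatch before glyphs
  groups <- xml2::xml_attr(xml2::xml_find_all(doc, "//d1:g", ns), "class")
  expect_equal(groups[1:3], c("markers", "region-hatch", "glyphs"))
})

test_that("saving the same figure twice is byte-identical (svg and pdf)", {
  pts <- make_small_points()
  fig <- render_plot(pts)
  a <- withr::local_tempfile(fileext = ".svg")
  b <- withr::local_tempfile(fileext = ".svg")
  save_figure(fig, a); save_figure(fig, b)
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
  pa <- withr::local_tempfile(fileext = ".pdf")
  pb <- withr::local_tempfile(fileext = ".pdf")
  save_figure(fig, pa); save_figure(fig, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
})

test_that("unsupported formats are rejected; png is written", {
  pts <- make_small_points()
  fig <- render_plot(pts)
  expect_error(save_figure(fig, "x.tiff"), "svg, png, pdf")
  f <- withr::local_tempfile(fileext = ".png")
  save_figure(fig, f, dpi = 72)
  expect_gt(file.size(f), 0)
  expect_s3_class(as_ggplot(fig), "ggplot")
})
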