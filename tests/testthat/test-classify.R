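test_that("occupancy grid bins points into half-open cells, conserving counts", {
  p1 <- point_table(0.5, 0.5, "a")
  g1 <- build_occupancy_grid(p1, bin_size = 1)
  expect_equal(nrow(g1$cells), 1L)
  expect_equal(g1$cells$count, 1L)

  p2 <- point_table(c(3, 3), c(7, 7), c("a", "a"))
  g2 <- build_occupancy_grid(p2, bin_size = 2)
  expect_equal(nrow(g2$cells), 1L)
  expect_equal(g2$cells$count, 2L)

  withr::local_seed(4)
  p3 <- point_table(runif(500, 0, 50), runif(500, 0, 50),
                    sample(c("a", "b"), 500, replace = TRUE))
  g3 <- build_occupancy_grid(p3, bin_size = 5)
  expect_equal(sum(g3$cells$count), 500L)
  for (g in c("a", "b")) {
    expect_equal(sum(g3$cells$count[g3$cells$group == g]),
                 sum(p3$group == g))
  }
  expect_error(build_occupancy_grid(p1, bin_size = 0), "bin_size")
})

test_that("cell assignment is left/bottom inclusive at boundaries", {
  pts <- point_table(c(0, 2, 4), c(0, 0, 0), rep("a", 3))
  g <- build_occupancy_grid(pts, bin_size = 2)
  expect_equal(sort(g$cells$i), c(0L, 1L, 2L))
  expect_equal(g$cells$count, c(1L, 1L, 1L))
})

test_that("isolation and unreachable thresholds give sparse labels", {
  canvas <- canvas_spec()
  # lone point far from its only same-group neighbor
  pts <- point_table(c(0, 100, 0, 100), c(0, 100, 1, 99),
                     c("a", "a", "b", "b"))
  lab <- classify_sparse_dense(pts, grid_config(density_threshold = 3),
                               canvas)
  expect_true(all(lab$label == "sparse"))
  # a group of 2 can never satisfy k = 3
  two <- point_table(c(0, 0.1, 50), c(0, 0.1, 50), c("a", "a", "b"))
  lab2 <- classify_sparse_dense(two, grid_config(density_threshold = 3),
                                canvas)
  expect_true(all(lab2$label[two$group == "a"] == "sparse"))
  expect_identical(attr(lab, "provenance"), "detector")
})

test_that("a dense lattice is fully recovered as dense", {
  # 10x10 lattice with spacing = bin_size/2: every 3x3 cell neighborhood
  # holds >= 5 points (brute-force oracle agrees)
  lat <- expand.grid(x = 0:9, y = 0:9)
  pts <- point_table(lat$x, lat$y, rep("a", 100))
  canvas <- canvas_spec()
  # display span is 432 pt over 9 data units; one lattice step = 48 pt
  cfg <- grid_config(bin_size = 96, density_threshold = 5,
                     min_cluster_cells = 2)
  lab <- classify_sparse_dense(pts, cfg, canvas)
  expect_true(all(lab$label == "dense"))
  expect_equal(oracle_classify(pts, cfg, canvas), lab$label)
})

test_that("labels always partition the points, per group and globally", {
  withr::local_seed(21)
  for (rep in 1:5) {
    pts <- random_config()
    lab <- classify_sparse_dense(pts, random_grid_config(), canvas_spec())
    expect_equal(nrow(lab), nrow(pts))
    expect_identical(lab$id, pts$id)
    expect_true(all(lab$label %in% c("dense", "sparse")))
  }
})

test_that("raising the density threshold never creates new dense points", {
  withr::local_seed(33)
  canvas <- canvas_spec()
  for (rep in 1:5) {
    pts <- random_config()
    prev_dense <- NULL
    for (k in 1:7) {
      cfg <- grid_config(bin_size = 22, density_threshold = k,
                         min_cluster_cells = 2)
      dense <- classify_sparse_dense(pts, cfg, canvas)$label == "dense"
      if (!is.null(prev_dense)) expect_true(all(prev_dense | !dense))
      prev_dense <- dense
    }
  }
})

test_that("classification matches the brute-force oracle on random configs", {
  withr::local_seed(55)
  canvas <- canvas_spec()
  for (rep in 1:10) {
    pts <- random_config()
    cfg <- random_grid_config()
    expect_identical(classify_sparse_dense(pts, cfg, canvas)$label,
                     oracle_classify(pts, cfg, canvas))
  }
})

test_that("each group's labels are independent of the other groups", {
  withr::local_seed(77)
  pts <- random_config()
  cfg <- grid_config(bin_size = 22, density_threshold = 3,
                     min_cluster_cells = 2)
  canvas <- canvas_spec()
  base <- classify_sparse_dense(pts, cfg, canvas)
  target <- point_groups(pts)[1L]
  # rename every other group; coordinates unchanged
  relabeled <- pts
  other <- relabeled$group != target
  relabeled$group[other] <- paste0("renamed_", relabeled$group[other])
  attr(relabeled, "groups") <- unique(relabeled$group)
  again <- classify_sparse_dense(relabeled, cfg, canvas)
  expect_identical(again$label[relabeled$group == target],
                   base$label[pts$group == target])
})

test_that("an explicit sparse list bypasses the detector entirely", {
  pts <- point_table(c(0, 0.1, 0.2, 5), c(0, 0.1, 0.2, 5),
                     rep("a", 4), id = c("p1", "p2", "p3", "p4"))
  all_sparse <- apply_sparse_override(pts, pts$id)
  expect_true(all(all_sparse$label == "sparse"))
  none <- apply_sparse_override(pts, character(0))
  expect_true(all(none$label == "dense"))
  expect_identical(attr(none, "provenance"), "override")
  expect_error(apply_sparse_override(pts, c("p1", "ghost")), "ghost")
})
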