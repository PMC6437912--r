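test_that("watershed handles degenerate and simple contour maps", {
  expect_equal(oversegment(matrix(0, 64, 64), 0, 0)$n_regions, 1)
  # one bright full-width line -> two basins split exactly on the line
  cmap <- matrix(0, 64, 64); cmap[32, ] <- 1
  rm2 <- oversegment(cmap, smoothing_sigma = 0, min_region_area = 0)
  expect_equal(rm2$n_regions, 2)
  expect_true(all(rm2$labels[32, ] == 0))
  expect_true(all(rm2$labels[-32, ] > 0))
  expect_true(validate_region_map(rm2))
})

test_that("oversegmented maps satisfy the closed single-pixel invariants", {
  set.seed(77)
  for (rep in 1:5) {
    h <- gaussian_blur(matrix(runif(96 * 96), 96, 96), 1.2)
    rm <- oversegment(h, smoothing_sigma = 0, min_region_area = 0)
    expect_true(validate_region_map(rm))
    rm2 <- oversegment(h, smoothing_sigma = 0, min_region_area = 25)
    expect_true(validate_region_map(rm2))
    expect_lte(rm2$n_regions, rm$n_regions)
  }
})

test_that("adjacency statistics match hand counts on a toy raster", {
  # 12x12, three vertical regions split by 0-columns
  lab <- matrix(0L, 12, 12)
  lab[, 1:3] <- 1L; lab[, 5:8] <- 2L; lab[, 10:12] <- 3L
  lab[, c(4, 9)] <- 0L
  rm <- muscleseg:::region_map(lab, 3L)
  contour <- matrix(0.25, 12, 12)
  contour[, 4] <- 1
  adj <- build_adjacency(rm, contour)
  expect_equal(nrow(adj), 2)
  expect_equal(adj$i, c(1L, 2L))
  expect_equal(adj$j, c(2L, 3L))
  expect_equal(adj$L, c(12L, 12L))
  expect_equal(adj$B, c(1, 0.25))
  # two regions split by a full-strength line
  lab2 <- matrix(1L, 10, 10); lab2[6, ] <- 0L; lab2[7:10, ] <- 2L
  adj2 <- build_adjacency(muscleseg:::region_map(lab2, 2L),
                          matrix(1, 10, 10))
  expect_equal(adj2$B, 1)
  expect_equal(adj2$L, 10L)
  # invalid region map is rejected
  bad <- matrix(1L, 8, 8); bad[, 5:8] <- 2L
  expect_error(build_adjacency(muscleseg:::region_map(bad, 2L),
                               matrix(0, 8, 8)), "closedness|4-adjacent")
})

test_that("threshold merging is greedy, conservative and nested", {
  # 4 regions in a row with known boundary strengths
  lab <- matrix(0L, 8, 17)
  lab[, 1:4] <- 1L; lab[, 6:8] <- 2L; lab[, 10:12] <- 3L; lab[, 14:17] <- 4L
  lab[, c(5, 9, 13)] <- 0L
  contour <- matrix(0, 8, 17)
  contour[, 5] <- 0.1; contour[, 9] <- 0.5; contour[, 13] <- 0.9
  rm <- muscleseg:::region_map(lab, 4L)
  adj <- build_adjacency(rm, contour)
  # threshold 0: unchanged
  expect_identical(threshold_merge(rm, adj, 0)$labels, rm$labels)
  # threshold 0.4: exactly the B = 0.1 edge merges
  t4 <- threshold_merge(rm, adj, 0.4)
  expect_equal(t4$n_regions, 3)
  expect_equal(unique(as.vector(t4$labels[, 1:8]))[
    unique(as.vector(t4$labels[, 1:8])) > 0], 1L)
  # threshold above all strengths: single region
  expect_equal(threshold_merge(rm, adj, 0.95)$n_regions, 1)
  # nestedness on random fixtures
  set.seed(5)
  for (rep in 1:3) {
    h <- gaussian_blur(matrix(runif(80 * 80), 80, 80), 1)
    rmr <- oversegment(h, 0, 0)
    adjr <- build_adjacency(rmr, matrix(pmin(pmax(h, 0), 1), 80, 80),
                            validate = FALSE)
    t1 <- threshold_merge(rmr, adjr, 0.3)
    t2 <- threshold_merge(rmr, adjr, 0.6)
    pair <- unique(cbind(as.vector(t1$labels), as.vector(t2$labels)))
    pair <- pair[pair[, 1] > 0 & pair[, 2] > 0, , drop = FALSE]
    expect_false(any(duplicated(pair[, 1])))
    # total boundary length never grows
    expect_lte(sum(t2$labels == 0), sum(t1$labels == 0))
    expect_lte(sum(t1$labels == 0), sum(rmr$labels == 0))
  }
})

test_that("label rasters round-trip through compact relabelling", {
  set.seed(6)
  h <- gaussian_blur(matrix(runif(64 * 64), 64, 64), 1)
  rm <- oversegment(h, 0, 10)
  cc <- matrix(muscleseg:::.label_components_cpp(
    as.integer(rm$labels > 0), 64, 64), 64, 64)
  expect_equal(max(cc), rm$n_regions)
})
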