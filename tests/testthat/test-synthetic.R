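test_that("generator is deterministic and produces valid ground truth", {
  spec <- synthetic_spec(n_cells = 50, height = 512, width = 512, seed = 7)
  out <- generate_image(spec)
  out2 <- generate_image(spec)
  expect_identical(out, out2)
  gt <- out$gt
  expect_equal(gt$n_cells, 50)
  expect_setequal(unique(as.vector(gt$labels)), 0:50)
  # boundary pixels between two distinct cells exist
  bm <- boundary_map(gt)
  expect_gt(sum(bm), 0)
  # image in range
  expect_true(all(out$image >= 0 & out$image <= 1))
  # every cell is 4-connected
  for (k in sample(1:50, 8)) {
    mask <- gt$labels == k
    cc <- matrix(muscleseg:::.label_components_cpp(as.integer(mask),
                                                   nrow(mask), ncol(mask)),
                 nrow(mask))
    expect_equal(max(cc), 1)
  }
})

test_that("single-cell image still contains background", {
  out <- generate_image(synthetic_spec(n_cells = 1, height = 64, width = 64))
  expect_setequal(unique(as.vector(out$gt$labels)), c(0L, 1L))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(height = 32), "64")
  expect_error(synthetic_spec(n_cells = 0), "n_cells")
  expect_error(synthetic_spec(boundary_contrast = 1.5), "contrast")
})

test_that("boundary_map marks interfaces only", {
  expect_equal(sum(boundary_map(matrix(0L, 32, 32))), 0)
  # one cell: the map is the ring of background pixels around the cell
  lab <- matrix(0L, 32, 32)
  lab[10:20, 10:20] <- 1L
  bm <- boundary_map(lab)
  ring <- matrix(0L, 32, 32)
  ring[9:21, 9:21] <- 1L
  ring[10:20, 10:20] <- 0L
  expect_identical(bm, ring)
  # every 1-pixel is 8-adjacent to at least 2 distinct labels (counting 0)
  gt <- fx_small()$gt
  bm2 <- boundary_map(gt)
  idx <- which(bm2 == 1)
  H <- nrow(bm2)
  y <- (idx - 1) %% H + 1; x <- (idx - 1) %/% H + 1
  ok <- vapply(seq_along(idx), function(i) {
    ys <- max(1, y[i] - 1):min(H, y[i] + 1)
    xs <- max(1, x[i] - 1):min(ncol(bm2), x[i] + 1)
    length(unique(as.vector(gt$labels[ys, xs]))) >= 2
  }, TRUE)
  expect_true(all(ok))
  # fraction of contour pixels strictly between 0 and 0.5 on a dense fixture
  frac <- mean(boundary_map(generate_image(easy_spec(9, n_cells = 50))$gt))
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
})

test_that("sample_patches stratifies and is reproducible", {
  sm <- fx_small()
  s1 <- sample_patches(sm$image, sm$gt, d_in = 32, d_out = 16, n = 40, seed = 3)
  s2 <- sample_patches(sm$image, sm$gt, d_in = 32, d_out = 16, n = 40, seed = 3)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$X, s2$X)
  expect_equal(nrow(s1$X), 40)
  expect_equal(ncol(s1$X), 32 * 32 * 13)
  expect_true(all(s1$Y %in% c(0L, 1L)))
  # stratification: at least a quarter of centre windows contain contour
  pos <- mean(rowSums(s1$Y) > 0)
  expect_gte(pos, 0.25)
  # labels must match the boundary map at the sampled window
  bm <- boundary_map(sm$gt)
  i <- 7
  cy <- s1$coords[i, "cy"]; cx <- s1$coords[i, "cx"]
  expect_equal(as.integer(s1$Y[i, ]),
               as.integer(bm[cy:(cy + 15), cx:(cx + 15)]))
  expect_error(sample_patches(sm$image[1:20, 1:20, ], sm$gt, n = 5),
               "smaller")
})

test_that("region training labels follow the IoU threshold", {
  sm <- fx_small()
  gl <- sm$gt$labels
  ch <- compute_channels(sm$image)
  contour <- matrix(0.5, nrow(gl), ncol(gl))
  # region map equal to the ground truth: every region positive
  rm_exact <- muscleseg:::region_map(gl, sm$gt$n_cells)
  ts <- sample_region_training_set(rm_exact, sm$gt, sm$image, contour,
                                   channels = ch)
  expect_true(all(ts$label == 1))
  expect_equal(ts$iou, rep(1, sm$gt$n_cells))
  # half of a cell fails at iou_pos = 0.7 (IoU = 0.5)
  half <- gl
  px <- which(gl == 1)
  H <- nrow(gl)
  xs <- (px - 1) %/% H + 1
  half[px[xs > stats::median(xs)]] <- 0L
  keep1 <- half
  keep1[keep1 != 1] <- 0L
  rm_half <- muscleseg:::region_map(keep1, 1L)
  th <- sample_region_training_set(rm_half, sm$gt, sm$image, contour,
                                   channels = ch)
  expect_lt(th$iou[1], 0.7)
  expect_equal(th$label[1], 0L)
  # region disjoint from all cells is negative
  bg <- matrix(0L, nrow(gl), ncol(gl))
  bg[gl == 0] <- 1L
  cc <- matrix(muscleseg:::.label_components_cpp(as.integer(bg), H, ncol(gl)),
               H, ncol(gl))
  rm_bg <- muscleseg:::region_map((cc == 1) * 1L, 1L)
  tb <- sample_region_training_set(rm_bg, sm$gt, sm$image, contour,
                                   channels = ch)
  expect_equal(tb$label[1], 0L)
})
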