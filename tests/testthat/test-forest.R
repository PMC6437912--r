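test_that("gini impurity matches hand values and rejects bad input", {
  expect_equal(gini_impurity(1), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(rep(0.25, 4)), 0.75)
  expect_error(gini_impurity(c(-0.1, 1.1)), "nonnegative")
  expect_error(gini_impurity(c(0.3, 0.3)), "sum")
})

test_that("information gain matches hand values", {
  # perfect split of a balanced parent: gain equals parent impurity
  expect_equal(information_gain(c(1, 1, 2, 2), c(1, 1), c(2, 2)), 0.5)
  # uninformative split: both children mirror the parent
  expect_equal(information_gain(c(1, 2, 1, 2), c(1, 2), c(1, 2)), 0)
  expect_error(information_gain(integer(0), integer(0), integer(0)), "empty")
  expect_error(information_gain(c(1, 2), c(1), c(1, 2)), "partition")
})

test_that("gain of any valid split is nonnegative (Gini concavity)", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:40, 1)
    parent <- sample(1:2, n, replace = TRUE)
    cut <- sample(n - 1, 1)
    g <- information_gain(parent, parent[1:cut], parent[(cut + 1):n])
    expect_gte(g, -1e-12)
  }
})

test_that("structured label mapping separates distinct patch families", {
  blank <- rep(0L, 64)
  full <- rep(1L, 64)
  half <- c(rep(0L, 32), rep(1L, 32))
  # blank and full have identical pair-comparison vectors -> one class
  cls <- map_labels_to_classes(rbind(blank, full), n_pairs = 128, seed = 2)
  expect_equal(cls[1], cls[2])
  # blank vs half-split must separate
  cls2 <- map_labels_to_classes(rbind(blank, blank, half, half),
                                n_pairs = 128, seed = 2)
  expect_length(unique(cls2[1:2]), 1)
  expect_length(unique(cls2[3:4]), 1)
  expect_false(cls2[1] == cls2[3])
  # identical labels map to one class without error
  expect_length(unique(map_labels_to_classes(rbind(half, half), seed = 1)), 1)
  # deterministic under a fixed seed
  expect_identical(cls2, map_labels_to_classes(rbind(blank, blank, half, half),
                                               n_pairs = 128, seed = 2))
})

test_that("best_split maximises gain over the exhaustive candidate grid", {
  set.seed(33)
  # 1-D perfectly separable data: gain equals parent impurity
  X <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1)
  cls <- rep(1:2, each = 10)
  sp <- best_split(X, cls, 1, n_thresholds = 16)
  expect_equal(sp$gain, 0.5)
  # constant features: no-split
  expect_null(best_split(matrix(1, 10, 2), rep(1:2, 5), 1:2))
  # brute-force oracle over all candidate (k, tau) pairs
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 5), 20, 5)
    cls <- sample(1:2, 20, replace = TRUE)
    if (length(unique(cls)) < 2) cls[1] <- 3 - cls[1]
    cand <- sort(sample(5, 3))
    sp <- best_split(X, cls, cand, n_thresholds = 8)
    best_gain <- -Inf
    for (k in cand) {
      qs <- unique(as.numeric(quantile(X[, k], probs = (1:8) / 9,
                                       names = FALSE, type = 1)))
      for (tau in qs) {
        left <- X[, k] < tau
        if (!any(left) || all(left)) next
        g <- information_gain(cls, cls[left], cls[!left])
        best_gain <- max(best_gain, g)
      }
    }
    if (is.null(sp)) expect_lte(best_gain, 1e-12)
    else expect_equal(sp$gain, best_gain)
  }
})

test_that("representative label is the member closest to the mean", {
  blank <- rep(0, 16); full <- rep(1, 16)
  expect_equal(select_representative_label(rbind(full)), full)
  expect_equal(select_representative_label(rbind(blank, blank, full)), blank)
  set.seed(4)
  Y <- matrix(rbinom(5 * 16, 1, 0.4), 5, 16)
  mu <- colMeans(Y)
  d <- rowSums(sweep(Y, 2, mu)^2)
  expect_equal(select_representative_label(Y), Y[which.min(d), ])
})

test_that("tree training reaches purity on separable patches and is seeded", {
  set.seed(8)
  n <- 40
  # two families: blank labels with low features, half-split labels with
  # high features (blank vs full would be indistinguishable under the
  # pairwise-comparison label mapping)
  X <- rbind(matrix(rnorm(n / 2 * 6, 0), ncol = 6),
             matrix(rnorm(n / 2 * 6, 6), ncol = 6))
  Y <- rbind(matrix(0L, n / 2, 16),
             cbind(matrix(0L, n / 2, 8), matrix(1L, n / 2, 8)))
  p <- forest_params(max_depth = 8, min_samples_leaf = 1)
  tr <- train_tree(X, Y, p, seed = 1)
  # predictions at training points are exactly right
  predict_one <- function(tree, x) {
    cur <- 1
    while (tree$nodes[cur, "leaf"] == 0) {
      cur <- if (x[tree$nodes[cur, "k"]] < tree$tau[cur])
        tree$nodes[cur, "left"] else tree$nodes[cur, "right"]
    }
    tree$leaves[tree$nodes[cur, "leaf"], ]
  }
  preds <- t(apply(X, 1, function(x) predict_one(tr, x)))
  expect_equal(preds, Y, ignore_attr = TRUE)
  # max_depth 0 gives a single leaf with the representative label
  tr0 <- train_tree(X, Y, forest_params(max_depth = 0), seed = 1)
  expect_equal(nrow(tr0$nodes), 1)
  expect_equal(tr0$nodes[1, "leaf"], 1, ignore_attr = TRUE)
  # fixed seeds give identical serialized models
  f1 <- train_forest(list(X = X, Y = Y, d_in = 4, d_out = 4),
                     forest_params(n_trees = 3, seed = 9))
  f2 <- train_forest(list(X = X, Y = Y, d_in = 4, d_out = 4),
                     forest_params(n_trees = 3, seed = 9))
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
})

test_that("contour prediction averages leaf votes exactly", {
  sm <- fx_small()
  # single-tree stub model with a constant split and known leaves
  d_in <- 32; d_out <- 16
  blank <- rep(0, d_out^2)
  full <- rep(1, d_out^2)
  mk_model <- function(leaves_mat, nodes, tau) {
    structure(list(
      trees = list(structure(list(
        nodes = nodes, tau = tau, leaves = leaves_mat), class = "srf_tree")),
      params = forest_params(n_trees = 1), d_in = d_in, d_out = d_out,
      n_channels = 13L, version = 1L), class = "forest_model")
  }
  # every leaf blank -> all-zero map
  m0 <- mk_model(rbind(blank), cbind(k = 0L, left = 0L, right = 0L, leaf = 1L),
                 NA_real_)
  cm <- predict_contours(sm$image, m0, stride = d_out)
  expect_equal(max(cm$values), 0)
  # threshold on channel 1 (Lab L): split at median lightness
  ch <- compute_channels(sm$image)
  tau <- stats::median(ch$values[, , 1])
  m1 <- mk_model(rbind(blank, full),
                 rbind(cbind(k = 1L, left = 2L, right = 3L, leaf = 0L),
                       cbind(k = 0L, left = 0L, right = 0L, leaf = 1L),
                       cbind(k = 0L, left = 0L, right = 0L, leaf = 2L)),
                 c(tau, NA, NA))
  cm1 <- predict_contours(sm$image, m1, stride = d_out)
  # hand-reassembled vote average for the stride = d_out grid
  H <- 160; W <- 160
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  off <- (d_in - d_out) / 2
  starts <- seq(-(d_out - 1), H - 1)
  starts <- starts[starts %% d_out == 0]
  mirror <- function(i, n) { i <- i %% (2 * n); ifelse(i >= n, 2 * n - i - 1, i) }
  for (cy in starts) for (cx in starts) {
    fy <- mirror(cy - off, H) + 1; fx <- mirror(cx - off, W) + 1
    v <- ch$values[fy, fx, 1]
    patch <- if (v < tau) 0 else 1
    ys <- cy:(cy + d_out - 1); xs <- cx:(cx + d_out - 1)
    ok_y <- ys >= 0 & ys < H; ok_x <- xs >= 0 & xs < W
    acc[ys[ok_y] + 1, xs[ok_x] + 1] <- acc[ys[ok_y] + 1, xs[ok_x] + 1] + patch
    cnt[ys[ok_y] + 1, xs[ok_x] + 1] <- cnt[ys[ok_y] + 1, xs[ok_x] + 1] + 1
  }
  expect_equal(cm1$values, acc / cnt)
  # worker count does not change the result
  cm4 <- predict_contours(sm$image, m1, stride = d_out, n_workers = 4)
  expect_identical(cm1$values, cm4$values)
  # monotonicity: adding an all-ones tree never decreases any pixel
  m2 <- mk_model(rbind(full), cbind(k = 0L, left = 0L, right = 0L, leaf = 1L),
                 NA_real_)
  m12 <- m1
  m12$trees <- c(m1$trees, m2$trees)
  cm12 <- predict_contours(sm$image, m12, stride = d_out)
  expect_true(all(cm12$values >= cm1$values - 1e-12))
  expect_true(all(cm12$values >= 0 & cm12$values <= 1))
  expect_error(predict_contours(sm$image, m1, stride = d_out + 1), "stride")
})
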