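test_that("merge tree has 2N-1 nodes and follows the greedy merge order", {
  # trivial single-region tree
  t1 <- build_tree(1, data.frame(i = integer(0), j = integer(0),
                                 B = numeric(0), L = numeric(0)))
  expect_equal(t1$n_nodes, 1)
  # weakest boundary merges first
  adj <- data.frame(i = c(1L, 2L), j = c(2L, 3L), B = c(0.1, 0.9), L = c(5, 5))
  tr <- build_tree(3, adj)
  expect_equal(tr$n_nodes, 5)
  first <- 4 # first internal node
  expect_setequal(c(tr$left[first], tr$right[first]), c(1, 2))
  # node count for a range of leaf counts (disconnected adjacency joined)
  for (n in c(2, 7, 20)) {
    inst <- rand_tree_instance(n, seed = n)
    expect_equal(inst$tree$n_nodes, 2 * n - 1)
    expect_equal(sort(inst$tree$leaf_regions), 1:n)
    # strict containment: every internal node's children are distinct nodes
    internal <- (n + 1):(2 * n - 1)
    expect_true(all(inst$tree$left[internal] != inst$tree$right[internal]))
  }
  # disconnected graph: still one tree via virtual joins
  td <- build_tree(4, data.frame(i = 1L, j = 2L, B = 0.2, L = 1))
  expect_equal(td$n_nodes, 7)
})

test_that("tree cutting decomposes at strong boundaries", {
  adj <- data.frame(i = c(1L, 2L, 3L), j = c(2L, 3L, 4L),
                    B = c(0.2, 0.8, 0.3), L = c(5, 5, 5))
  tr <- build_tree(4, adj)
  # threshold 1: single tree
  expect_length(cut_tree(tr, adj, 1), 1)
  # threshold 0 with positive strengths: all singletons
  expect_length(cut_tree(tr, adj, 0), 4)
  # threshold 0.5 cuts exactly the 0.8 edge
  f <- cut_tree(tr, adj, 0.5)
  expect_length(f, 2)
  leafsets <- lapply(f, function(t) sort(t$leaf_regions))
  expect_setequal(lapply(leafsets, paste, collapse = ","),
                  list("1,2", "3,4"))
  # leaf sets always partition the base regions
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    inst <- rand_tree_instance(n, seed = 100 + rep)
    adj_r <- data.frame(i = inst$tree$leaf_regions[inst$model$edges$li],
                        j = inst$tree$leaf_regions[inst$model$edges$lj],
                        B = inst$model$edges$B, L = inst$model$edges$L)
    adj_r <- data.frame(i = pmin(adj_r$i, adj_r$j), j = pmax(adj_r$i, adj_r$j),
                        B = adj_r$B, L = adj_r$L)
    f <- cut_tree(inst$tree, adj_r, runif(1))
    expect_setequal(unlist(lapply(f, `[[`, "leaf_regions")), 1:n)
  }
})

test_that("region features match hand values on simple shapes", {
  H <- 64; W <- 64
  ch <- compute_channels(array(0.5, c(H, W, 3)))
  contour <- matrix(0.2, H, W)
  # 5x5 square: area 25, crack perimeter 20 faces scaled by pi/4
  sq <- outer(1:H, 1:W, function(y, x) y %in% 10:14 & x %in% 20:24)
  f <- region_features(which(sq), ch, contour, H, W)
  expect_equal(f[["area"]], 25)
  expect_equal(f[["perimeter"]], 20 * pi / 4)
  expect_equal(f[["sd_L"]], 0)
  expect_equal(f[["sd_a"]], 0)
  expect_equal(f[["contour_ring"]], 0.2)
  expect_equal(f[["eccentricity"]], 0)
  # disk: circularity close to the isoperimetric limit
  d <- outer(1:H, 1:W, function(y, x) (y - 32)^2 + (x - 32)^2 <= 15^2)
  fd <- region_features(which(d), ch, contour, H, W)
  expect_gte(fd[["circularity"]], 0.85)
  expect_lte(fd[["circularity"]], 1)
  expect_gte(fd[["solidity"]], 0.9)
  # elongated region is eccentric
  e <- outer(1:H, 1:W, function(y, x) y %in% 30:33 & x %in% 5:60)
  fe <- region_features(which(e), ch, contour, H, W)
  expect_gt(fe[["eccentricity"]], 0.9)
})

test_that("aggregated node features agree with direct per-node computation", {
  sm <- fx_small()
  ch <- compute_channels(sm$image)
  contour <- muscleseg:::contour_map(matrix(0.3, 160, 160))
  rm <- oversegment(gaussian_blur(matrix(as.numeric(boundary_map(sm$gt)),
                                         160, 160), 1), 0, 20)
  adj <- build_adjacency(rm, contour, validate = FALSE)
  tree <- build_tree(rm, adj)
  fm <- muscleseg:::node_feature_matrix(tree, rm$labels, ch, contour)
  px <- muscleseg:::node_pixels(tree, rm$labels)
  for (nd in unique(c(1, tree$n_leaves, tree$n_leaves + 1, tree$n_nodes))) {
    direct <- region_features(px[[nd]], ch, contour, 160, 160)
    expect_equal(fm[nd, ], direct, tolerance = 1e-8)
  }
})

test_that("region scorer is seeded, probabilistic, and rejects one class", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 4), 10, 4))
  colnames(X) <- c("a", "b", "c", "d")
  y <- rep(0:1, each = 10)
  expect_error(train_region_scorer(X, rep(1, 20)), "positive and")
  s1 <- train_region_scorer(X, y, ntree = 51, seed = 7)
  s2 <- train_region_scorer(X, y, ntree = 51, seed = 7)
  p1 <- muscleseg:::score_features(s1, X)
  expect_identical(p1, muscleseg:::score_features(s2, X))
  # training positives score high with an overfit scorer
  expect_true(all(p1[y == 1] >= 0.5))
  # identical feature vectors with conflicting labels: the averaged vote is
  # strictly between 0 and 1
  dup <- matrix(1, 1, 4, dimnames = list(NULL, colnames(X)))
  Xc <- rbind(dup[rep(1, 6), ], X)
  yc <- c(rep(0:1, 3), y)
  sc <- train_region_scorer(Xc, yc, ntree = 101, seed = 1)
  pc <- muscleseg:::score_features(sc, dup)
  expect_true(all(pc > 0 & pc < 1))
})

test_that("energy matches closed forms and rejects overlap", {
  adj <- data.frame(li = 1L, lj = 2L, B = log(2), L = 3)
  tr <- build_tree(2, data.frame(i = 1L, j = 2L, B = 0.5, L = 3))
  em <- energy_model(c(0.5, 0.5, 0.5), adj, mu = 2, epsilon = 1e-6)
  # mu = 0: energy is constant across labelings when all scores are 0.5
  em0 <- energy_model(c(0.5, 0.5, 0.5), adj, mu = 0, epsilon = 1e-6)
  E_all <- vapply(list(integer(0), 1L, c(1L, 2L), 3L), energy, 0,
                  tree = tr, model = em0)
  expect_equal(diff(range(E_all)), 0)
  expect_equal(E_all[1], 3 * -log(0.5 + 1e-6))
  # pairwise closed form: mu * exp(-B) * L = 2 * 0.5 * 3 = 3
  expect_equal(energy(1L, tr, em) - energy(1L, tr, em0), 3)
  # V(B = 0, L = 10, mu = 1) = 10
  em10 <- energy_model(c(0.5, 0.5, 0.5),
                       data.frame(li = 1L, lj = 2L, B = 0, L = 10), mu = 1)
  em10z <- energy_model(c(0.5, 0.5, 0.5),
                        data.frame(li = 1L, lj = 2L, B = 0, L = 10), mu = 0)
  expect_equal(energy(2L, tr, em10) - energy(2L, tr, em10z), 10)
  # ancestor and descendant cannot both be selected
  expect_error(energy(c(1L, 3L), tr, em), "antichain")
})

test_that("exact inference matches the independent enumeration oracle", {
  for (trial in 1:30) {
    n <- sample(2:8, 1)
    for (mu in c(0, 0.1, 1)) {
      inst <- rand_tree_instance(n, seed = trial * 7 + n, mu = mu)
      got <- infer_exact(inst$tree, inst$model)
      want <- oracle_infer(inst$tree, inst$model)
      expect_equal(got$energy, want$energy, tolerance = 1e-10)
      expect_true(check_antichain_public(inst$tree, got$selected))
    }
  }
  # single-leaf decision follows the larger unary likelihood
  t1 <- build_tree(1, data.frame(i = integer(0), j = integer(0),
                                 B = numeric(0), L = numeric(0)))
  em1 <- energy_model(0.9, data.frame(li = integer(0), lj = integer(0),
                                      B = numeric(0), L = numeric(0)))
  expect_equal(infer_exact(t1, em1)$selected, 1L)
  # sibling leaves beat a weak parent
  tr2 <- build_tree(2, data.frame(i = 1L, j = 2L, B = 0.5, L = 5))
  em2 <- energy_model(c(0.9, 0.9, 0.1),
                      data.frame(li = 1L, lj = 2L, B = 0.5, L = 5), mu = 0)
  expect_equal(infer_exact(tr2, em2)$selected, c(1L, 2L))
  # guard against oversized subtrees
  big <- rand_tree_instance(14, seed = 1)
  expect_error(infer_exact(big$tree, big$model, max_leaves = 12), "infer_fast")
})

test_that("raising a node's score never drops it from the exact solution", {
  for (trial in 1:10) {
    n <- sample(3:7, 1)
    inst <- rand_tree_instance(n, seed = 400 + trial, mu = 0)
    sol <- infer_exact(inst$tree, inst$model)
    if (length(sol$selected) == 0) next
    i <- sol$selected[1]
    m2 <- inst$model
    m2$scores[i] <- min(1, m2$scores[i] + runif(1) * (1 - m2$scores[i]))
    sol2 <- infer_exact(inst$tree, m2)
    expect_true(i %in% sol2$selected)
  }
})

test_that("fast inference is exact without pairwise terms and never worse than its DP stage", {
  for (trial in 1:20) {
    n <- sample(3:12, 1)
    inst <- rand_tree_instance(n, seed = 900 + trial, mu = 0)
    f <- infer_fast(inst$tree, inst$model)
    e <- infer_exact(inst$tree, inst$model, max_leaves = 12)
    expect_equal(f$energy, e$energy, tolerance = 1e-10)
  }
  # with pairwise terms the local search stays feasible and close to exact
  rel_gap <- vapply(1:25, function(trial) {
    inst <- rand_tree_instance(10, seed = 2000 + trial, mu = 0.5)
    f <- infer_fast(inst$tree, inst$model)
    e <- infer_exact(inst$tree, inst$model)
    expect_true(check_antichain_public(inst$tree, f$selected))
    expect_gte(f$energy, e$energy - 1e-10)
    (f$energy - e$energy) / max(abs(e$energy), 1e-9)
  }, 0)
  expect_lt(stats::median(rel_gap), 0.05)
})

test_that("selected segments form disjoint connected cells", {
  # three regions separated by single-pixel boundary lines
  lab <- matrix(0L, 20, 20)
  lab[2:9, 2:9] <- 1L    # top-left
  lab[2:9, 11:18] <- 2L  # top-right (col 10 separates)
  lab[11:18, 2:18] <- 3L # bottom (row 10 separates)
  rm <- muscleseg:::region_map(lab, 3L)
  adj <- data.frame(i = c(1L, 1L), j = c(2L, 3L), B = c(0.1, 0.9), L = c(8, 8))
  tr <- build_tree(3, adj)
  # nothing selected -> all-background raster
  seg0 <- select_segments(list(tr), list(list(selected = integer(0))), rm)
  expect_equal(max(seg0$labels), 0)
  # root selected -> one cell covering all base regions
  segr <- select_segments(list(tr), list(list(selected = tr$n_nodes)), rm)
  expect_equal(nrow(segr$cells), 1)
  expect_true(all(segr$labels[lab > 0] == 1))
  # merged node absorbs only the boundary interior to it
  sel12 <- which(tr$left == 1 & tr$right == 2 |
                 tr$left == 2 & tr$right == 1)
  seg12 <- select_segments(list(tr), list(list(selected = sel12)), rm)
  expect_equal(nrow(seg12$cells), 1)
  expect_true(all(seg12$labels[lab == 3] == 0))
})
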