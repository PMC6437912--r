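# Shared fixtures and independent oracles. Heavy objects (trained models,
# large synthetic images) are built once per test run and cached.

.fx <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# the study conditions for end-to-end checks: clean, well-contrasted
# synthetic muscle images
easy_spec <- function(seed, n_cells = 30, side = 512) {
  synthetic_spec(n_cells = n_cells, height = side, width = side,
                 boundary_contrast = 0.5, boundary_break_prob = 0,
                 seed = seed)
}

fx_train_pair <- function() fx_get("train_pair", function() {
  list(generate_image(easy_spec(101)), generate_image(easy_spec(102)))
})

fx_models <- function() fx_get("models", function() {
  train_segmentation_models(fx_train_pair(), pipeline_config())
})

fx_test_image <- function() fx_get("test_image", function() {
  generate_image(easy_spec(103))
})

fx_small <- function() fx_get("small", function() {
  generate_image(synthetic_spec(n_cells = 8, height = 160, width = 160,
                                boundary_contrast = 0.7,
                                boundary_break_prob = 0, seed = 5))
})

# canonical relabelling: cell ids in raster-scan first-encounter order
canon_labels <- function(lab) {
  v <- as.vector(lab)
  u <- unique(v[v > 0])
  out <- v
  out[v > 0] <- match(v[v > 0], u)
  matrix(out, nrow(lab))
}

# random region-adjacency instance and its merge tree
rand_tree_instance <- function(n_leaves, seed, mu = 0.1) {
  set.seed(seed)
  edges <- NULL
  if (n_leaves > 1)
    for (i in 2:n_leaves) edges <- rbind(edges, c(sample(i - 1, 1), i))
  if (n_leaves > 2) {
    extra <- matrix(sample(n_leaves, 2 * sample(0:3, 1), replace = TRUE),
                    ncol = 2)
    edges <- rbind(edges, extra)
  }
  if (is.null(edges)) {
    adj <- data.frame(i = integer(0), j = integer(0), B = numeric(0),
                      L = numeric(0))
  } else {
    e <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    adj <- unique(data.frame(i = pmin(e[, 1], e[, 2]),
                             j = pmax(e[, 1], e[, 2])))
    adj$B <- runif(nrow(adj))
    adj$L <- sample(1:20, nrow(adj), replace = TRUE)
    adj <- adj[order(adj$i, adj$j), ]
  }
  tree <- build_tree(n_leaves, adj)
  edges_local <- if (nrow(adj)) data.frame(
    li = match(adj$i, tree$leaf_regions),
    lj = match(adj$j, tree$leaf_regions), B = adj$B, L = adj$L)
  else data.frame(li = integer(0), lj = integer(0), B = numeric(0),
                  L = numeric(0))
  model <- energy_model(runif(tree$n_nodes), edges_local, mu = mu)
  list(tree = tree, model = model)
}

# --- independent inference oracle -----------------------------------------
# Enumerates antichains by a frontier recursion (select a frontier node and
# drop its subtree, or replace it by its children) and scores each labeling
# with a from-scratch energy using per-leaf ancestor walks. Shares no code
# with the package's bottom-up enumeration / cover-propagation energies.

oracle_antichains <- function(tree) {
  rec <- function(frontier) {
    if (length(frontier) == 0) return(list(integer(0)))
    f <- frontier[1]
    rest <- frontier[-1]
    with_f <- lapply(rec(rest), function(s) c(f, s))
    without <- if (f <= tree$n_leaves) rec(rest)
    else rec(c(tree$left[f], tree$right[f], rest))
    c(with_f, without)
  }
  rec(tree$n_nodes)
}

oracle_energy <- function(selected, tree, model) {
  u <- 0
  for (i in seq_len(tree$n_nodes)) {
    s <- model$scores[i]
    u <- u + if (i %in% selected) -log(s + model$epsilon)
    else -log(1 - s + model$epsilon)
  }
  owner_of <- function(l) {
    while (l != 0) {
      if (l %in% selected) return(l)
      l <- tree$parent[l]
      if (l == 0) break
    }
    0L
  }
  v <- 0
  if (model$mu > 0 && nrow(model$edges) > 0) {
    for (r in seq_len(nrow(model$edges))) {
      oi <- owner_of(model$edges$li[r])
      oj <- owner_of(model$edges$lj[r])
      if (oi != oj)
        v <- v + model$mu * exp(-model$edges$B[r]) * model$edges$L[r]
    }
  }
  u + v
}

oracle_infer <- function(tree, model) {
  sets <- oracle_antichains(tree)
  E <- vapply(sets, oracle_energy, 0, tree = tree, model = model)
  i <- which.min(E)
  list(selected = sort(sets[[i]]), energy = E[i])
}

check_antichain_public <- function(tree, selected)
  muscleseg:::check_antichain(tree, selected)

# rank-based AUROC (probability a random positive outranks a random negative)
auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
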