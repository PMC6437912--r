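# Structured random forest contour detector.
#
# Each tree maps a d_in x d_in x 13 feature window to a d_out x d_out binary
# contour patch stored at its leaves. Because structured labels cannot be
# scored directly, at every node the label patches falling there are mapped
# to two discrete classes (pairwise pixel comparisons projected on their
# first principal direction) and the split is chosen by Gini information
# gain over those classes. Prediction averages all overlapping leaf votes.

#' Gini impurity of a class distribution
#'
#' \eqn{H = \sum_l c_l (1 - c_l)} for class proportions \eqn{c_l}.
#'
#' @param proportions nonnegative numeric vector summing to 1.
#' @return impurity in `[0, 1 - 1/L]`.
#' @examples
#' gini_impurity(c(0.5, 0.5)) # 0.5
#' @export
gini_impurity <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be nonnegative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1", call. = FALSE)
  sum(proportions * (1 - proportions))
}

prop_of <- function(classes, levels) {
  tabulate(match(classes, levels), length(levels)) / length(classes)
}

#' Information gain of a split
#'
#' Gini impurity of the parent minus the size-weighted impurities of the
#' children. For a valid split of the same data this is nonnegative (up to
#' floating point) by concavity of the Gini index.
#'
#' @param parent_classes,left_classes,right_classes class label vectors;
#'   left and right must partition the parent.
#' @return the gain, a scalar.
#' @export
information_gain <- function(parent_classes, left_classes, right_classes) {
  np <- length(parent_classes)
  if (np == 0) stop("empty parent", call. = FALSE)
  if (length(left_classes) + length(right_classes) != np)
    stop("left and right must partition the parent", call. = FALSE)
  lev <- sort(unique(parent_classes))
  h <- function(cl) if (length(cl) == 0) 0 else gini_impurity(prop_of(cl, lev))
  h(parent_classes) -
    length(left_classes) / np * h(left_classes) -
    length(right_classes) / np * h(right_classes)
}

#' Map structured labels to two discrete classes
#'
#' For each label patch, a binary comparison vector over `n_pairs` sampled
#' pixel pairs (same value vs. different) is computed; the vectors are
#' centred and projected on their first principal direction, and the sign of
#' the projection defines two classes. Identical labels always share a class.
#'
#' @param labels matrix with one flattened binary label patch per row (or a
#'   list of such patches).
#' @param n_pairs number of sampled pixel pairs.
#' @param seed integer seed.
#' @return integer class vector (values 1/2).
#' @export
map_labels_to_classes <- function(labels, n_pairs = 256, seed = 1L) {
  if (is.list(labels)) labels <- do.call(rbind, lapply(labels, as.vector))
  stopifnot(is.matrix(labels), nrow(labels) >= 1, n_pairs >= 1)
  P <- ncol(labels)
  with_seed(seed, {
    p1 <- sample.int(P, n_pairs, replace = TRUE)
    p2 <- sample.int(P, n_pairs, replace = TRUE)
    bump <- p1 == p2
    p2[bump] <- (p2[bump] %% P) + 1L
    Z <- (labels[, p1, drop = FALSE] != labels[, p2, drop = FALSE]) * 1
    Zc <- sweep(Z, 2, colMeans(Z))
    v <- rep(1 / sqrt(n_pairs), n_pairs)
    for (it in 1:8) {
      u <- as.vector(Zc %*% v)
      v2 <- as.vector(crossprod(Zc, u))
      nv <- sqrt(sum(v2^2))
      if (nv < 1e-12) break
      v <- v2 / nv
    }
    proj <- as.vector(Zc %*% v)
    ifelse(proj >= 0, 1L, 2L)
  })
}

#' Best axis-aligned split over candidate features
#'
#' Scans per-feature threshold candidates (quantiles of the observed values)
#' and returns the (feature, threshold) pair maximising the information
#' gain, with ties broken by lowest feature index then lowest threshold.
#'
#' @param X feature matrix (samples x features).
#' @param classes discrete class labels from [map_labels_to_classes()].
#' @param candidate_features column indices to consider.
#' @param n_thresholds threshold candidates per feature.
#' @param min_child minimum samples required in each child.
#' @return list with `k` (feature index into `X`), `tau`, `gain`, or `NULL`
#'   when no split has positive gain ("no-split").
#' @export
best_split <- function(X, classes, candidate_features, n_thresholds = 16,
                       min_child = 1) {
  m <- nrow(X)
  if (m < 2 || length(unique(classes)) < 2)
    stop("need >= 2 samples with >= 2 classes", call. = FALSE)
  c1 <- classes == classes[order(classes)][1]
  n1 <- sum(c1)
  h2 <- function(a, n) { # Gini of a binary split part from counts
    p <- ifelse(n > 0, a / n, 0)
    2 * p * (1 - p)
  }
  hp <- h2(n1, m)
  best <- NULL
  for (k in sort(candidate_features)) {
    v <- X[, k]
    # type-1 quantiles are observed data values, so every candidate
    # threshold realises an actual left/right partition of the samples
    qs <- unique(as.numeric(quantile(v, probs = seq_len(n_thresholds) /
                                       (n_thresholds + 1), names = FALSE,
                                     type = 1)))
    M <- outer(v, qs, "<")
    nL <- colSums(M)
    n1L <- colSums(M & c1)
    nR <- m - nL
    gain <- hp - nL / m * h2(n1L, nL) - nR / m * h2(n1 - n1L, nR)
    gain[nL < min_child | nR < min_child] <- -Inf
    gi <- which(gain > if (is.null(best)) 1e-12 else best$gain)
    if (length(gi) > 0) {
      # first maximum -> lowest tau among ties (qs ascending)
      i <- gi[match(max(gain[gi]), gain[gi])]
      best <- list(k = k, tau = qs[i], gain = gain[i])
    }
  }
  best
}

#' Representative structured label of a set
#'
#' Returns the member label closest (squared distance) to the element-wise
#' mean of the labels, first occurrence on ties.
#'
#' @param labels matrix with one flattened label per row, or list of patches.
#' @return the chosen label as a numeric vector.
#' @export
select_representative_label <- function(labels) {
  if (is.list(labels)) labels <- do.call(rbind, lapply(labels, as.vector))
  stopifnot(is.matrix(labels), nrow(labels) >= 1)
  mu <- colMeans(labels)
  d <- rowSums(sweep(labels, 2, mu)^2)
  labels[which.min(d), ]
}

#' Training parameters for the structured forest
#'
#' @param n_trees number of trees.
#' @param sample_frac,feature_frac per-tree fractions of training rows and
#'   feature dimensions.
#' @param max_depth,min_samples_leaf stopping criteria.
#' @param n_node_features candidate features examined per node.
#' @param n_thresholds threshold candidates per feature.
#' @param n_pairs pixel pairs for the structured-label class mapping.
#' @param seed base seed; tree `j` uses `seed + j`.
#' @return list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 8, sample_frac = 0.5, feature_frac = 0.25,
                          max_depth = 32, min_samples_leaf = 8,
                          n_node_features = 64, n_thresholds = 16,
                          n_pairs = 256, seed = 1L) {
  structure(list(n_trees = n_trees, sample_frac = sample_frac,
                 feature_frac = feature_frac, max_depth = max_depth,
                 min_samples_leaf = min_samples_leaf,
                 n_node_features = n_node_features,
                 n_thresholds = n_thresholds, n_pairs = n_pairs,
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Train a single structured decision tree
#'
#' Recursive splitting with the structured-label class mapping recomputed at
#' every node; stops on depth, leaf size, purity, or no-split. The returned
#' tree is in flattened form: a `nodes` integer matrix with columns
#' `k` (global feature index), `left`, `right`, `leaf` (row into `leaves`,
#' 0 for internal nodes), a `tau` vector, and a `leaves` matrix of
#' representative label patches.
#'
#' @param X feature matrix (rows = samples), `Y` binary label matrix.
#' @param params [forest_params()].
#' @param seed tree seed.
#' @param rows,feats optional row/feature subsets (defaults: all).
#' @return list of class `srf_tree`.
#' @export
train_tree <- function(X, Y, params = forest_params(), seed = 1L,
                       rows = seq_len(nrow(X)), feats = seq_len(ncol(X))) {
  if (length(rows) == 0) stop("empty training set", call. = FALSE)
  env <- new.env()
  env$k <- integer(0); env$tau <- numeric(0)
  env$left <- integer(0); env$right <- integer(0); env$leaf <- integer(0)
  env$leaves <- list()
  env$counter <- 0L
  min_leaf <- params$min_samples_leaf

  new_node <- function() {
    i <- length(env$k) + 1L
    env$k[i] <- 0L; env$tau[i] <- NA_real_
    env$left[i] <- 0L; env$right[i] <- 0L; env$leaf[i] <- 0L
    i
  }
  make_leaf <- function(i, idx) {
    env$leaves[[length(env$leaves) + 1L]] <- select_representative_label(
      Y[idx, , drop = FALSE])
    env$leaf[i] <- length(env$leaves)
  }
  grow <- function(idx, depth) {
    i <- new_node()
    env$counter <- env$counter + 1L
    node_seed <- mix_seed(seed, env$counter)
    Yn <- Y[idx, , drop = FALSE]
    pure <- all(Yn == rep(Yn[1, ], each = nrow(Yn)))
    if (length(idx) < 2 * min_leaf || depth >= params$max_depth || pure) {
      make_leaf(i, idx); return(i)
    }
    classes <- map_labels_to_classes(Yn, params$n_pairs, node_seed)
    if (length(unique(classes)) < 2) { make_leaf(i, idx); return(i) }
    cand <- with_seed(node_seed, {
      sample(feats, min(params$n_node_features, length(feats)))
    })
    sp <- best_split(X[idx, , drop = FALSE], classes, cand,
                     params$n_thresholds, min_child = min_leaf)
    if (is.null(sp)) { make_leaf(i, idx); return(i) }
    env$k[i] <- sp$k; env$tau[i] <- sp$tau
    go_left <- X[idx, sp$k] < sp$tau
    env$left[i] <- grow(idx[go_left], depth + 1L)
    env$right[i] <- grow(idx[!go_left], depth + 1L)
    i
  }
  grow(rows, 0L)
  nodes <- cbind(k = env$k, left = env$left, right = env$right, leaf = env$leaf)
  leaves <- do.call(rbind, env$leaves)
  structure(list(nodes = nodes, tau = env$tau, leaves = leaves),
            class = "srf_tree")
}

#' Train the structured random forest
#'
#' Each tree draws its own row and feature subsets (seeded by
#' `params$seed + tree index`) and is grown independently.
#'
#' @param samples a `patch_samples` object from [sample_patches()] (or a
#'   list with `X`, `Y`, `d_in`, `d_out`).
#' @param params [forest_params()].
#' @return object of class `forest_model`.
#' @export
train_forest <- function(samples, params = forest_params()) {
  X <- samples$X; Y <- samples$Y
  if (is.null(X) || nrow(X) < params$min_samples_leaf)
    stop("training set too small", call. = FALSE)
  n <- nrow(X); P <- ncol(X)
  trees <- lapply(seq_len(params$n_trees), function(j) {
    sj <- params$seed + j
    sub <- with_seed(sj, {
      list(rows = sort(sample.int(n, max(2, round(params$sample_frac * n)))),
           feats = sort(sample.int(P, max(2, round(params$feature_frac * P)))))
    })
    train_tree(X, Y, params, seed = sj, rows = sub$rows, feats = sub$feats)
  })
  structure(list(trees = trees, params = params,
                 d_in = samples$d_in, d_out = samples$d_out,
                 n_channels = 13L, version = 1L),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model: %d trees, d_in=%d, d_out=%d>\n",
              length(x$trees), x$d_in, x$d_out))
  invisible(x)
}

contour_map <- function(values) {
  stopifnot(is.matrix(values), all(is.finite(values)),
            min(values) >= 0, max(values) <= 1)
  structure(list(values = values), class = "contour_map")
}

#' Predict a contour probability map
#'
#' Slides the label window over a stride grid (aligned to `origin` in global
#' coordinates so tile crops vote on the same grid as the full image), lets
#' every tree vote its leaf patch, and averages all votes covering each
#' pixel. Image borders are mirrored for feature lookups. The result is
#' independent of `n_workers`.
#'
#' @param image H x W x 3 array in `[0, 1]`, or a precomputed channel stack.
#' @param model a `forest_model`.
#' @param stride grid step in pixels, must not exceed `d_out`.
#' @param n_workers worker processes for patch-chunk parallelism.
#' @param origin global (y, x) 0-based offset of `image`'s top-left pixel.
#' @return object of class `contour_map` with `values` in `[0, 1]`.
#' @export
predict_contours <- function(image, model, stride = 8, n_workers = 1,
                             origin = c(0L, 0L)) {
  stopifnot(inherits(model, "forest_model"))
  if (stride > model$d_out) stop("stride > d_out leaves coverage gaps", call. = FALSE)
  ch <- if (inherits(image, "channel_stack")) image else compute_channels(image)
  H <- dim(ch$values)[1]; W <- dim(ch$values)[2]
  if (min(H, W) < model$d_in) stop("image smaller than d_in", call. = FALSE)
  d_out <- model$d_out
  grid_1d <- function(n, o) {
    s <- seq(-(d_out - 1), n - 1)
    s[(s + o) %% stride == 0]
  }
  sy <- grid_1d(H, origin[1]); sx <- grid_1d(W, origin[2])
  # column-major position order: consistent between a crop and the full image
  cy <- rep(sy, times = length(sx))
  cx <- rep(sx, each = length(sy))
  trees <- lapply(model$trees, unclass)
  run <- function(i1, i2) {
    .forest_vote_cpp(as.numeric(ch$values), H, W, 13L,
                     model$d_in, d_out,
                     as.integer(cy[i1:i2]), as.integer(cx[i1:i2]), trees)
  }
  n <- length(cy)
  if (n_workers <= 1) {
    res <- run(1L, n)
    acc <- res$acc; cnt <- res$cnt
  } else {
    bounds <- floor(seq(0, n, length.out = n_workers + 1))
    parts <- parallel::mclapply(seq_len(n_workers), function(w) {
      run(bounds[w] + 1L, bounds[w + 1L])
    }, mc.cores = n_workers)
    # leaf votes are 0/1 so these sums are exact integers: the combined
    # result is bit-identical to the sequential one for any chunking
    acc <- Reduce(`+`, lapply(parts, `[[`, "acc"))
    cnt <- Reduce(`+`, lapply(parts, `[[`, "cnt"))
  }
  contour_map(matrix(acc / pmax(cnt, 1), H, W))
}
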