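# Hierarchical tree-based region selection.
#
# Base regions are agglomerated (weakest shared boundary first) into a
# binary merge tree with 2N-1 nodes. Every node is a candidate cell and
# receives a probability from a region-scoring classifier. Final cells are
# the node set minimising a CRF energy
#   E = sum_i U_i + sum_(i,j) mu * exp(-B_ij) * L_ij
# subject to the non-overlap (antichain) constraint: no selected node may be
# an ancestor of another. Strong contour evidence cuts the tree into
# independent subtrees so inference parallelises and stays exact.

# --- region tree -----------------------------------------------------------

new_region_tree <- function(n_leaves, leaf_regions, parent, left, right,
                            merge_B) {
  structure(list(n_leaves = n_leaves, leaf_regions = leaf_regions,
                 parent = parent, left = left, right = right,
                 merge_B = merge_B, n_nodes = 2L * n_leaves - 1L),
            class = "region_tree")
}

#' @export
print.region_tree <- function(x, ...) {
  cat(sprintf("<region_tree: %d leaves, %d nodes>\n", x$n_leaves, x$n_nodes))
  invisible(x)
}

# agglomerate; allowed_max limits which edges may merge (Inf = full tree).
# Returns list of region_tree, one per resulting component; join = TRUE
# additionally chains components with virtual B = 1 merges into one tree.
agglomerate <- function(n_regions, adjacency, allowed_max = Inf, join = TRUE) {
  res <- .merge_greedy_cpp(n_regions, as.integer(adjacency$i),
                           as.integer(adjacency$j),
                           as.numeric(adjacency$B), as.numeric(adjacency$L),
                           allowed_max, FALSE)
  node_of <- seq_len(n_regions) # root region id -> tree node id (global ids)
  uf <- res$roots               # extended by the virtual joins below
  nm <- length(res$merge_r)
  left <- right <- integer(0)
  merge_B <- numeric(0)
  nxt <- n_regions
  record <- function(r0, s0, B) {
    nxt <<- nxt + 1L
    a <- min(r0, s0); b <- max(r0, s0)
    left[nxt - n_regions] <<- node_of[a]
    right[nxt - n_regions] <<- node_of[b]
    merge_B[nxt - n_regions] <<- B
    node_of[a] <<- nxt # surviving root is always min(r0, s0)
  }
  if (nm > 0) for (m in seq_len(nm))
    record(res$merge_r[m], res$merge_s[m], res$merge_B[m])
  roots <- sort(unique(uf))
  if (join && length(roots) > 1) {
    for (s in roots[-1]) record(roots[1], s, 1)
    roots <- roots[1]
  }
  # split the global node table into per-component trees with local ids
  trees <- lapply(roots, function(r) {
    root_node <- node_of[r]
    # collect nodes of this component
    stack <- root_node; nodes <- integer(0)
    while (length(stack) > 0) {
      nd <- stack[[1]]; stack <- stack[-1]
      nodes <- c(nodes, nd)
      if (nd > n_regions)
        stack <- c(stack, left[nd - n_regions], right[nd - n_regions])
    }
    leaves <- sort(nodes[nodes <= n_regions])
    internals <- sort(nodes[nodes > n_regions])
    nl <- length(leaves)
    loc <- integer(max(nodes))
    loc[leaves] <- seq_len(nl)
    loc[internals] <- nl + seq_along(internals)
    lf <- rg <- integer(2 * nl - 1)
    mb <- rep(NA_real_, 2 * nl - 1)
    par <- integer(2 * nl - 1)
    for (nd in internals) {
      i <- loc[nd]
      lf[i] <- loc[left[nd - n_regions]]
      rg[i] <- loc[right[nd - n_regions]]
      mb[i] <- merge_B[nd - n_regions]
      par[lf[i]] <- i; par[rg[i]] <- i
    }
    new_region_tree(nl, leaves, par, lf, rg, mb)
  })
  trees
}

#' Build the binary region merge tree
#'
#' Agglomerates base regions pair-wise, always merging the adjacent pair
#' with minimum boundary strength (merged-edge strengths are length-weighted
#' means; ties broken by smallest region-id pair). Components disconnected
#' in the adjacency graph are joined in index order with virtual strength-1
#' merges, so the result always has `2 * N - 1` nodes: leaves `1..N` are the
#' base regions, internal nodes follow in merge order, the last node is the
#' root.
#'
#' @param regions a `region_map` (or a leaf count).
#' @param adjacency output of [build_adjacency()].
#' @return a `region_tree`.
#' @export
build_tree <- function(regions, adjacency) {
  n <- if (inherits(regions, "region_map")) regions$n_regions else as.integer(regions)
  stopifnot(n >= 1)
  agglomerate(n, adjacency, allowed_max = Inf, join = TRUE)[[1]]
}

#' Cut the region tree into independent subtrees by contour strength
#'
#' Re-runs the agglomeration but refuses to merge across any boundary whose
#' (current, length-weighted) strength exceeds `cut_threshold`: adjacent
#' regions with strong common contour evidence are treated as separate
#' cells, so the selection problem decomposes into independent subtrees
#' whose leaf sets partition the base regions. Pairwise energy terms between
#' different subtrees are dropped.
#'
#' @param tree the full `region_tree` (supplies the leaf count).
#' @param adjacency base-region adjacency used to build the tree.
#' @param cut_threshold strength level in `[0, 1]`.
#' @return list of `region_tree` subtrees.
#' @export
cut_tree <- function(tree, adjacency, cut_threshold) {
  stopifnot(cut_threshold >= 0, cut_threshold <= 1)
  agglomerate(tree$n_leaves, adjacency, allowed_max = cut_threshold,
              join = FALSE)
}

# --- region features -------------------------------------------------------

REGION_FEATURE_NAMES <- c(
  "area", "perimeter", "circularity", "solidity", "eccentricity",
  "mean_L", "sd_L", "mean_a", "sd_a", "mean_b", "sd_b",
  "contour_ring", "contour_interior", "contour_ratio"
)

#' Shape and appearance features of a candidate region
#'
#' Fixed-order vector: area; perimeter (crack-edge count corrected by
#' \eqn{\pi/4} so a digital disk scores its smooth perimeter); circularity
#' \eqn{4\pi A / P^2} clamped to `[0, 1]`; solidity (area over convex hull
#' area); eccentricity from central moments; mean and standard deviation of
#' each CIE-Lab channel inside the region; mean contour value on the
#' region's one-pixel boundary ring and in its interior; and the guarded
#' ring/interior contour ratio. 14 features total.
#'
#' @param pixels linear (column-major) pixel indices of the region.
#' @param channels a `channel_stack` for the image.
#' @param contour aligned `contour_map` or matrix.
#' @param H,W raster dimensions.
#' @return named numeric vector.
#' @export
region_features <- function(pixels, channels, contour, H, W) {
  buf <- new.env(parent = emptyenv())
  buf$mask <- logical(H * W)
  region_features_impl(pixels, channels, contour, H, W, buf)
}

# `buf$mask` is a reusable all-FALSE logical(H * W) scratch buffer held in
# an environment so it is flipped in place: batch callers (one per tree)
# avoid allocating a fresh image-sized mask for every region
region_features_impl <- function(pixels, channels, contour, H, W, buf) {
  stopifnot(length(pixels) >= 1)
  vals <- if (inherits(contour, "contour_map")) contour$values else contour
  y <- (pixels - 1L) %% H + 1L
  x <- (pixels - 1L) %/% H + 1L
  buf$mask[pixels] <- TRUE
  on.exit(buf$mask[pixels] <- FALSE)
  out_nb <- function(dy, dx) {
    yy <- y + dy; xx <- x + dx
    bad <- yy < 1 | yy > H | xx < 1 | xx > W
    res <- logical(length(pixels))
    res[bad] <- TRUE
    ii <- !bad
    res[ii] <- !buf$mask[(xx[ii] - 1L) * H + yy[ii]]
    res
  }
  outs <- cbind(out_nb(-1, 0), out_nb(1, 0), out_nb(0, -1), out_nb(0, 1))
  crack <- sum(outs)
  ring <- rowSums(outs) > 0
  area <- length(pixels)
  perim <- crack * pi / 4
  circ <- clamp(4 * pi * area / perim^2, 0, 1)
  # solidity via convex hull of the boundary ring
  ry <- y[ring]; rx <- x[ring]
  sol <- 1
  if (length(ry) >= 3) {
    h <- chull(rx, ry)
    hx <- rx[h]; hy <- ry[h]
    a2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    hull_area <- a2 + length(h) / 2 + 1 # Pick-style pixel-count estimate
    sol <- clamp(area / hull_area, 0, 1)
  }
  # eccentricity from second central moments
  my <- mean(y); mx <- mean(x)
  m20 <- mean((x - mx)^2); m02 <- mean((y - my)^2); m11 <- mean((x - mx) * (y - my))
  tr <- m20 + m02
  dt <- sqrt(max(0, (m20 - m02)^2 + 4 * m11^2))
  l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(clamp(1 - l2 / l1, 0, 1))
  cv <- channels$values
  plane <- H * W
  labstats <- unlist(lapply(1:3, function(c) {
    v <- cv[pixels + (c - 1L) * plane]
    s <- if (length(v) > 1) sd(v) else 0
    c(mean(v), s)
  }))
  cr <- mean(vals[pixels[ring]])
  ci <- if (any(!ring)) mean(vals[pixels[!ring]]) else cr
  ratio <- (cr + 0.01) / (ci + 0.01)
  stats::setNames(c(area, perim, circ, sol, ecc, labstats, cr, ci, ratio),
                  REGION_FEATURE_NAMES)
}

# pixel index lists per base region id (names are region ids)
region_pixels <- function(region_labels) {
  px <- split(seq_along(region_labels), as.vector(region_labels))
  px[["0"]] <- NULL
  px
}

# pixel index list per tree node (leaves from the region map, internal
# nodes as unions of their children), in local node order
node_pixels <- function(tree, region_labels, px = NULL) {
  if (is.null(px)) px <- region_pixels(region_labels)
  out <- vector("list", tree$n_nodes)
  for (i in seq_len(tree$n_leaves))
    out[[i]] <- px[[as.character(tree$leaf_regions[i])]]
  if (tree$n_nodes > tree$n_leaves) {
    for (i in (tree$n_leaves + 1):tree$n_nodes)
      out[[i]] <- c(out[[tree$left[i]]], out[[tree$right[i]]])
  }
  out
}

# --- region scorer ---------------------------------------------------------

#' Train the cell-region scoring classifier
#'
#' A standard probability-outputting random forest over
#' [region_features()], trained on positive (cell-like, IoU-matched) and
#' negative region examples; see [sample_region_training_set()].
#'
#' @param features feature matrix.
#' @param label binary 0/1 vector.
#' @param ntree forest size.
#' @param seed integer seed; fixed seed gives identical scorers.
#' @return object of class `region_scorer`.
#' @export
train_region_scorer <- function(features, label, ntree = 200, seed = 1L) {
  if (length(unique(label)) < 2)
    stop("need at least one positive and one negative example", call. = FALSE)
  rf <- with_seed(seed, {
    randomForest::randomForest(x = as.data.frame(features),
                               y = factor(label, levels = c(0, 1)),
                               ntree = ntree)
  })
  structure(list(rf = rf, version = 1L), class = "region_scorer")
}

#' Score every node of a region tree
#'
#' @param tree a `region_tree`.
#' @param scorer a `region_scorer`.
#' @param region_labels label raster the tree's leaves refer to.
#' @param channels channel stack of the image.
#' @param contour aligned contour map.
#' @return numeric vector of cell probabilities, one per tree node.
#' @export
score_nodes <- function(tree, scorer, region_labels, channels, contour,
                        stats = NULL) {
  feats <- node_feature_matrix(tree, region_labels, channels, contour, stats)
  score_features(scorer, feats)
}

# Per-base-region sufficient statistics for region features. Sibling
# regions are never 4-adjacent (separated by boundary pixels), so area,
# crack-edge count, boundary-ring membership, contour sums, colour sums and
# coordinate moments are all exactly additive over a node's leaves, and the
# convex hull of a union is the hull of the children's hull points.
leaf_stats <- function(region_labels, channels, contour) {
  vals <- if (inherits(contour, "contour_map")) contour$values else contour
  H <- nrow(region_labels); W <- ncol(region_labels)
  lv <- as.vector(region_labels)
  nz <- lv > 0
  # faces to non-member pixels per pixel (4-neighbourhood, borders count)
  fc <- matrix(0L, H, W)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nbl <- matrix(0L, H, W)
    ys <- seq_len(H) + d[1]; xs <- seq_len(W) + d[2]
    okY <- ys >= 1 & ys <= H; okX <- xs >= 1 & xs <= W
    nbl[okY, okX] <- region_labels[ys[okY], xs[okX]]
    fc <- fc + (region_labels > 0 & nbl != region_labels)
  }
  fcv <- as.vector(fc)[nz]
  ring <- fcv > 0
  ids <- lv[nz]
  y <- ((which(nz) - 1L) %% H + 1L)
  x <- ((which(nz) - 1L) %/% H + 1L)
  cv <- as.vector(vals)[nz]
  plane <- H * W
  Lc <- channels$values[which(nz)]
  ac <- channels$values[which(nz) + plane]
  bc <- channels$values[which(nz) + 2L * plane]
  M <- cbind(area = 1, crack = fcv, ring = ring + 0,
             ring_contour = ring * cv, contour = cv,
             L = Lc, a = ac, b = bc, L2 = Lc^2, a2 = ac^2, b2 = bc^2,
             sy = y, sx = x, syy = y^2, sxx = x^2, sxy = x * y)
  agg <- rowsum(M, ids)
  ord <- as.integer(rownames(agg))
  out <- matrix(0, max(ord), ncol(M))
  colnames(out) <- colnames(M)
  out[ord, ] <- agg
  # per-region convex hull vertices of the boundary ring
  ry <- y[ring]; rx <- x[ring]; rid <- ids[ring]
  hulls <- vector("list", max(ord))
  sp <- split(seq_along(rid), rid)
  for (k in names(sp)) {
    ii <- sp[[k]]
    pts <- cbind(rx[ii], ry[ii])
    h <- if (nrow(pts) >= 3) pts[chull(pts), , drop = FALSE] else pts
    hulls[[as.integer(k)]] <- h
  }
  list(mat = out, hulls = hulls)
}

# features for one node from aggregated sufficient statistics
features_from_stats <- function(s, hull_pts) {
  a <- s[["area"]]
  perim <- s[["crack"]] * pi / 4
  circ <- clamp(4 * pi * a / perim^2, 0, 1)
  sol <- 1
  if (!is.null(hull_pts) && nrow(hull_pts) >= 3) {
    h <- hull_pts[chull(hull_pts), , drop = FALSE]
    hx <- h[, 1]; hy <- h[, 2]
    a2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    hull_area <- a2 + nrow(h) / 2 + 1
    sol <- clamp(a / hull_area, 0, 1)
  }
  my <- s[["sy"]] / a; mx <- s[["sx"]] / a
  m20 <- s[["sxx"]] / a - mx^2
  m02 <- s[["syy"]] / a - my^2
  m11 <- s[["sxy"]] / a - mx * my
  tr <- m20 + m02
  dt <- sqrt(max(0, (m20 - m02)^2 + 4 * m11^2))
  l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(clamp(1 - l2 / l1, 0, 1))
  labf <- unlist(lapply(c("L", "a", "b"), function(ch) {
    mu <- s[[ch]] / a
    ss <- s[[paste0(ch, "2")]]
    sdv <- if (a > 1) sqrt(max(0, (ss - a * mu^2) / (a - 1))) else 0
    c(mu, sdv)
  }))
  rc <- s[["ring"]]
  cr <- s[["ring_contour"]] / rc
  ci <- if (a > rc) (s[["contour"]] - s[["ring_contour"]]) / (a - rc) else cr
  ratio <- (cr + 0.01) / (ci + 0.01)
  stats::setNames(c(a, perim, circ, sol, ecc, labf, cr, ci, ratio),
                  REGION_FEATURE_NAMES)
}

node_feature_matrix <- function(tree, region_labels, channels, contour,
                                stats = NULL) {
  if (is.null(stats)) stats <- leaf_stats(region_labels, channels, contour)
  n <- tree$n_nodes
  S <- matrix(0, n, ncol(stats$mat))
  colnames(S) <- colnames(stats$mat)
  S[seq_len(tree$n_leaves), ] <- stats$mat[tree$leaf_regions, , drop = FALSE]
  hp <- vector("list", n)
  for (i in seq_len(tree$n_leaves)) hp[[i]] <- stats$hulls[[tree$leaf_regions[i]]]
  if (n > tree$n_leaves) for (i in (tree$n_leaves + 1):n) {
    S[i, ] <- S[tree$left[i], ] + S[tree$right[i], ]
    hl <- rbind(hp[[tree$left[i]]], hp[[tree$right[i]]])
    hp[[i]] <- if (nrow(hl) >= 3) hl[chull(hl), , drop = FALSE] else hl
  }
  feats <- t(vapply(seq_len(n), function(i) {
    features_from_stats(S[i, ], hp[[i]])
  }, numeric(length(REGION_FEATURE_NAMES))))
  colnames(feats) <- REGION_FEATURE_NAMES
  feats
}

score_features <- function(scorer, feats) {
  as.numeric(predict(scorer$rf, as.data.frame(feats), type = "prob")[, "1"])
}

# --- energy and inference --------------------------------------------------

#' Energy model for hierarchical region selection
#'
#' @param scores per-node cell probabilities in `[0, 1]` (length `2N - 1`).
#' @param edges data.frame of adjacent leaf pairs with columns `li`, `lj`
#'   (local leaf indices), `B`, `L`.
#' @param mu pairwise trade-off constant (>= 0).
#' @param epsilon log guard (> 0).
#' @return list of class `energy_model`.
#' @export
energy_model <- function(scores, edges, mu = 0.1, epsilon = 1e-6) {
  stopifnot(all(scores >= 0), all(scores <= 1), mu >= 0, epsilon > 0)
  structure(list(scores = scores, edges = edges, mu = mu, epsilon = epsilon),
            class = "energy_model")
}

# ancestors of each node including itself, leaf-up order
ancestor_list <- function(tree) {
  lapply(seq_len(tree$n_nodes), function(i) {
    a <- i
    while (tree$parent[i] != 0) { i <- tree$parent[i]; a <- c(a, i) }
    a
  })
}

# for every node, the selected ancestor strictly above it (0 if none), via
# one root-down sweep: internal nodes always have larger indices than their
# children, so descending index order is a topological order
strict_above <- function(tree, sel) {
  n <- tree$n_nodes
  above <- integer(n)
  if (n > tree$n_leaves) for (i in n:(tree$n_leaves + 1)) {
    a <- if (sel[i]) i else above[i]
    above[tree$left[i]] <- a
    above[tree$right[i]] <- a
  }
  above
}

check_antichain <- function(tree, selected) {
  if (length(selected) < 2) return(TRUE)
  sel <- logical(tree$n_nodes)
  sel[selected] <- TRUE
  above <- strict_above(tree, sel)
  !any(sel & above > 0)
}

# owner (selected covering node id, 0 = background) per leaf
leaf_owners <- function(tree, selected) {
  sel <- logical(tree$n_nodes)
  sel[selected] <- TRUE
  above <- strict_above(tree, sel)
  l <- seq_len(tree$n_leaves)
  ifelse(sel[l], l, above[l])
}

#' CRF energy of a labeling
#'
#' Unary terms: `-log(s_i + eps)` for selected nodes and `-log(1 - s_i +
#' eps)` otherwise, summed over all `2N - 1` nodes. Pairwise terms: for
#' every adjacent leaf pair whose induced cell labels differ,
#' `mu * exp(-B) * L` is added.
#'
#' @param selected integer vector of selected node ids (an antichain).
#' @param tree a `region_tree`.
#' @param model an [energy_model()].
#' @return the energy, a finite scalar.
#' @export
energy <- function(selected, tree, model) {
  if (!check_antichain(tree, selected))
    stop("selected nodes violate the antichain (non-overlap) constraint",
         call. = FALSE)
  s <- model$scores; eps <- model$epsilon
  u1 <- -log(s + eps); u0 <- -log(1 - s + eps)
  E <- sum(u0) + sum(u1[selected] - u0[selected])
  if (model$mu > 0 && nrow(model$edges) > 0) {
    own <- leaf_owners(tree, selected)
    differ <- own[model$edges$li] != own[model$edges$lj]
    E <- E + sum(model$mu * exp(-model$edges$B[differ]) * model$edges$L[differ])
  }
  E
}

# all antichain selections of the subtree rooted at `node`, as a list of
# integer vectors (includes the empty selection)
antichains_below <- function(tree, node) {
  if (node <= tree$n_leaves) return(list(integer(0), node))
  Ls <- antichains_below(tree, tree$left[node])
  Rs <- antichains_below(tree, tree$right[node])
  out <- vector("list", 1L + length(Ls) * length(Rs))
  out[[1]] <- node
  k <- 1L
  for (a in Ls) for (b in Rs) {
    k <- k + 1L
    out[[k]] <- c(a, b)
  }
  out
}

# vectorised energies for a list of selections
energy_batch <- function(sel_list, tree, model) {
  s <- model$scores; eps <- model$epsilon
  u1 <- -log(s + eps); u0 <- -log(1 - s + eps)
  M <- matrix(FALSE, length(sel_list), tree$n_nodes)
  for (i in seq_along(sel_list)) M[i, sel_list[[i]]] <- TRUE
  E <- as.vector(M %*% (u1 - u0)) + sum(u0)
  if (model$mu > 0 && nrow(model$edges) > 0) {
    n <- tree$n_nodes
    Above <- matrix(0L, nrow(M), n)
    if (n > tree$n_leaves) for (i in n:(tree$n_leaves + 1)) {
      a <- ifelse(M[, i], i, Above[, i])
      Above[, tree$left[i]] <- a
      Above[, tree$right[i]] <- a
    }
    l <- seq_len(tree$n_leaves)
    own <- matrix(0L, nrow(M), tree$n_leaves)
    for (j in l) own[, j] <- ifelse(M[, j], j, Above[, j])
    w <- model$mu * exp(-model$edges$B) * model$edges$L
    dif <- own[, model$edges$li, drop = FALSE] != own[, model$edges$lj, drop = FALSE]
    E <- E + as.vector(dif %*% w)
  }
  E
}

lex_less <- function(a, b) {
  # is sorted set a lexicographically smaller than sorted set b?
  n <- min(length(a), length(b))
  if (n > 0) for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Exact inference by antichain enumeration
#'
#' Enumerates every antichain labeling of the subtree and returns the global
#' minimiser of [energy()]; ties resolved toward the lexicographically
#' smallest selected set.
#'
#' @param tree a `region_tree` with at most `max_leaves` leaves.
#' @param model an [energy_model()].
#' @param max_leaves enumeration guard (default 12).
#' @return list with `selected` (sorted node ids) and `energy`.
#' @export
infer_exact <- function(tree, model, max_leaves = 12) {
  if (tree$n_leaves > max_leaves)
    stop("subtree too large for exhaustive inference; use infer_fast()",
         call. = FALSE)
  sels <- antichains_below(tree, tree$n_nodes)
  sels <- lapply(sels, function(s) sort(as.integer(s)))
  E <- energy_batch(sels, tree, model)
  best <- which(E == min(E))
  pick <- best[1]
  for (b in best[-1]) if (lex_less(sels[[b]], sels[[pick]])) pick <- b
  list(selected = sels[[pick]], energy = E[pick])
}

#' Fast approximate inference for large subtrees
#'
#' Stage 1 solves the unary-only problem exactly by dynamic programming on
#' the tree (at each node: select it, or take the best of its children's
#' solutions, with background costs accounted). Stage 2 is a greedy local
#' search over single-node moves (flip, promote-to-parent,
#' demote-to-children) accepting only strict full-energy decreases. The
#' result always satisfies the antichain constraint, and with `mu = 0` it is
#' exactly optimal.
#'
#' @param tree a `region_tree`.
#' @param model an [energy_model()].
#' @return list with `selected` and `energy`.
#' @export
infer_fast <- function(tree, model) {
  s <- model$scores; eps <- model$epsilon
  u1 <- -log(s + eps); u0 <- -log(1 - s + eps)
  n <- tree$n_nodes
  # sum of u0 over each subtree
  subt_u0 <- u0
  for (i in seq_len(n)) if (i > tree$n_leaves)
    subt_u0[i] <- u0[i] + subt_u0[tree$left[i]] + subt_u0[tree$right[i]]
  best <- numeric(n)     # best energy of subtree under antichain freedom
  take <- logical(n)     # whether selecting node i itself is optimal there
  for (i in seq_len(n)) {
    cost_sel <- u1[i] + subt_u0[i] - u0[i]
    if (i <= tree$n_leaves) {
      best[i] <- min(cost_sel, u0[i])
      take[i] <- cost_sel < u0[i]
    } else {
      cost_pass <- u0[i] + best[tree$left[i]] + best[tree$right[i]]
      best[i] <- min(cost_sel, cost_pass)
      take[i] <- cost_sel < cost_pass
    }
  }
  selected <- integer(0)
  stack <- n
  while (length(stack) > 0) {
    i <- stack[1]; stack <- stack[-1]
    if (take[i]) selected <- c(selected, i)
    else if (i > tree$n_leaves) stack <- c(stack, tree$left[i], tree$right[i])
  }
  selected <- sort(selected)
  cur_E <- energy(selected, tree, model)
  if (model$mu > 0) {
    anc <- ancestor_list(tree)
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        props <- list()
        if (i %in% selected) {
          props <- c(props, list(setdiff(selected, i)))
          if (i > tree$n_leaves)
            props <- c(props, list(sort(c(setdiff(selected, i),
                                          tree$left[i], tree$right[i]))))
        } else {
          blocked <- any(selected %in% anc[[i]])
          below <- selected[vapply(selected, function(s2)
            i %in% anc[[s2]], TRUE)]
          if (!blocked && length(below) == 0)
            props <- c(props, list(sort(c(selected, i))))
          if (length(below) > 0 && !any(setdiff(selected, below) %in% anc[[i]]))
            props <- c(props, list(sort(c(setdiff(selected, below), i))))
        }
        for (p in props) {
          Ep <- energy(p, tree, model)
          if (Ep < cur_E - 1e-12) {
            selected <- p; cur_E <- Ep; improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
  }
  list(selected = selected, energy = cur_E)
}

#' Assemble selected tree nodes into a cell label raster
#'
#' Each selected node becomes one output cell covering its base regions;
#' unselected leaves stay background. Boundary pixels interior to a cell
#' (separating two of its own base regions) are absorbed into the cell;
#' boundaries between different cells or facing background are kept.
#'
#' @param subtrees list of `region_tree` subtrees (from [cut_tree()]).
#' @param labelings list of inference results aligned with `subtrees`.
#' @param regions the base `region_map`.
#' @return list with `labels` (integer raster, 0 background) and `cells`
#'   (data.frame: `cell`, `subtree`, `node`, `area`).
#' @export
select_segments <- function(subtrees, labelings, regions) {
  labels <- regions$labels
  H <- nrow(labels); W <- ncol(labels)
  out <- matrix(0L, H, W)
  px_all <- region_pixels(labels)
  cells <- list()
  cid <- 0L
  for (t in seq_along(subtrees)) {
    tr <- subtrees[[t]]
    sel <- labelings[[t]]$selected
    if (length(sel) == 0) next
    px <- node_pixels(tr, labels, px_all)
    for (nd in sel) {
      cid <- cid + 1L
      out[px[[nd]]] <- cid
      cells[[cid]] <- data.frame(cell = cid, subtree = t, node = nd,
                                 area = length(px[[nd]]))
    }
  }
  if (cid > 0) {
    out <- absorb_internal(out, labels)
    # a cell assembled from merged base regions can carry one-pixel
    # satellites stranded in boundary junction pockets; keep only its
    # largest 4-connected component (scan order on ties)
    for (id in seq_len(cid)) {
      px <- which(out == id)
      if (length(px) == 0) next
      y <- (px - 1L) %% H + 1L; x <- (px - 1L) %/% H + 1L
      y0 <- min(y); x0 <- min(x)
      sub <- matrix(0L, max(y) - y0 + 1L, max(x) - x0 + 1L)
      sub[cbind(y - y0 + 1L, x - x0 + 1L)] <- 1L
      cc <- matrix(.label_components_cpp(sub, nrow(sub), ncol(sub)),
                   nrow(sub), ncol(sub))
      if (max(cc) > 1) {
        main <- which.max(tabulate(cc[cc > 0]))
        drop_local <- which(cc > 0 & cc != main)
        ly <- (drop_local - 1L) %% nrow(sub) + 1L
        lx <- (drop_local - 1L) %/% nrow(sub) + 1L
        out[cbind(ly + y0 - 1L, lx + x0 - 1L)] <- 0L
        cells[[id]]$area <- sum(out == id)
      }
    }
  }
  list(labels = out,
       cells = if (cid > 0) do.call(rbind, cells)
               else data.frame(cell = integer(0), subtree = integer(0),
                               node = integer(0), area = integer(0)))
}

# absorb boundary pixels whose non-zero 8-neighbours belong to one cell via
# at least two distinct base regions (i.e. lines interior to a merged cell)
absorb_internal <- function(cells, base_labels) {
  H <- nrow(cells); W <- ncol(cells)
  for (pass in 1:2) {
    cmin <- matrix(Inf, H, W); cmax <- matrix(-Inf, H, W)
    bmin <- matrix(Inf, H, W); bmax <- matrix(-Inf, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
      okY <- ys >= 1 & ys <= H; okX <- xs >= 1 & xs <= W
      cn <- matrix(0L, H, W); bn <- matrix(0L, H, W)
      cn[okY, okX] <- cells[ys[okY], xs[okX]]
      bn[okY, okX] <- base_labels[ys[okY], xs[okX]]
      hit <- cn > 0
      cmin[hit] <- pmin(cmin[hit], cn[hit])
      cmax[hit] <- pmax(cmax[hit], cn[hit])
      bmin[hit] <- pmin(bmin[hit], bn[hit])
      bmax[hit] <- pmax(bmax[hit], bn[hit])
    }
    absorb <- cells == 0 & is.finite(cmin) & cmin == cmax & bmin != bmax
    if (!any(absorb)) break
    cells[absorb] <- as.integer(cmin[absorb])
  }
  cells
}
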