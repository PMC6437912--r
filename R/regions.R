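# Region candidate generation: watershed oversegmentation of the contour
# map into closed, single-pixel-bounded base regions, the region adjacency
# statistics (boundary strength B, boundary length L), and greedy
# boundary-strength merging (the thresholdable region hierarchy).

region_map <- function(labels, n_regions = max(labels), owners = NULL) {
  stopifnot(is.matrix(labels))
  structure(list(labels = labels, n_regions = as.integer(n_regions),
                 owners = owners),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map %d x %d, %d regions>\n",
              nrow(x$labels), ncol(x$labels), x$n_regions))
  invisible(x)
}

# Derive a region map from a full-coverage label raster: a pixel becomes a
# boundary (0) pixel iff its down or right neighbour survives with a
# different label (the crack between regions, drawn on the upper/left
# side; see src/watershed.cpp), so separating lines are single-pixel wide
# by construction and no two distinct regions are ever 4-adjacent. Region
# ids are the 4-connected components of the surviving pixels, in
# raster-scan order. `owners` resolves every boundary pixel back to its
# owning region (preferring a 4-neighbour of the same full-raster label),
# which lets merging relabel the full raster and re-derive boundaries
# without any geometry surgery.
derive_regions <- function(full) {
  H <- nrow(full); W <- ncol(full)
  zl <- matrix(.derive_crack_cpp(as.integer(full), H, W), H, W)
  cc <- matrix(.label_components_cpp(as.integer(zl != 0), H, W), H, W)
  owners <- cc
  shift_val <- function(m, dy, dx, fill = 0L) {
    out <- matrix(fill, H, W)
    ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
    okY <- ys >= 1 & ys <= H; okX <- xs >= 1 & xs <= W
    out[okY, okX] <- m[ys[okY], xs[okX]]
    out
  }
  dirs <- list(c(-1, 0), c(0, -1), c(1, 0), c(0, 1)) # up, left, down, right
  repeat { # same-label neighbours first, in fixed direction priority
    todo <- owners == 0
    if (!any(todo)) break
    changed <- FALSE
    for (d in dirs) {
      no <- shift_val(owners, d[1], d[2])
      nf <- shift_val(full, d[1], d[2], fill = -1L)
      take <- todo & owners == 0 & no > 0 & nf == full
      if (any(take)) { owners[take] <- no[take]; changed <- TRUE }
    }
    if (!changed) break
  }
  repeat { # orphans (fully-eroded fragments): smallest resolved neighbour
    todo <- owners == 0
    if (!any(todo)) break
    best <- matrix(.Machine$integer.max, H, W)
    for (d in dirs) {
      no <- shift_val(owners, d[1], d[2])
      upd <- todo & no > 0 & no < best
      best[upd] <- no[upd]
    }
    got <- todo & best < .Machine$integer.max
    if (!any(got)) break
    owners[got] <- best[got]
  }
  region_map(cc, max(cc), owners)
}

#' Validate region-map invariants
#'
#' Checks that every region is a 4-connected component of the non-boundary
#' pixels (closedness: removing 0-pixels yields exactly `n_regions`
#' components, each carrying a single label), that no two distinct labels
#' are 4-adjacent, and that the boundary skeleton is single-pixel wide (no
#' interior 2 x 2 all-zero block; image-border blocks are allowed).
#'
#' @param rm a `region_map`.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
validate_region_map <- function(rm) {
  labels <- rm$labels
  H <- nrow(labels); W <- ncol(labels)
  cc <- matrix(.label_components_cpp(as.integer(labels > 0), H, W), H, W)
  ncc <- max(cc)
  if (ncc != rm$n_regions)
    stop(sprintf("closedness violated: %d components vs %d regions", ncc,
                 rm$n_regions), call. = FALSE)
  agg <- tapply(as.vector(labels)[cc > 0], as.vector(cc)[cc > 0],
                function(v) length(unique(v)))
  if (any(agg != 1))
    stop("a connected component carries more than one region label", call. = FALSE)
  right <- labels[, -1] != labels[, -W] & labels[, -1] > 0 & labels[, -W] > 0
  down <- labels[-1, ] != labels[-H, ] & labels[-1, ] > 0 & labels[-H, ] > 0
  if (any(right) || any(down))
    stop("two distinct regions are 4-adjacent", call. = FALSE)
  if (H > 2 && W > 2) {
    z <- labels == 0
    blk <- z[-H, -W] & z[-1, -W] & z[-H, -1] & z[-1, -1]
    blk[c(1, H - 1), ] <- FALSE
    blk[, c(1, W - 1)] <- FALSE
    if (any(blk))
      stop("boundary is not single-pixel wide (interior 2x2 zero block)",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Watershed oversegmentation of a contour map
#'
#' Floods the (optionally smoothed) contour map from its regional minima
#' with a deterministic priority queue; where basins meet, single-pixel
#' watershed lines (label 0) are left so every region is closed. Regions
#' smaller than `min_region_area` are merged into the neighbour with the
#' weakest shared boundary.
#'
#' @param contour a `contour_map` (or numeric matrix in `[0, 1]`).
#' @param smoothing_sigma Gaussian smoothing applied before flooding.
#' @param min_region_area minimum region area in pixels.
#' @return a `region_map`.
#' @export
oversegment <- function(contour, smoothing_sigma = 1, min_region_area = 30) {
  vals <- if (inherits(contour, "contour_map")) contour$values else contour
  stopifnot(is.matrix(vals), all(is.finite(vals)))
  H <- nrow(vals); W <- ncol(vals)
  h <- if (smoothing_sigma > 0) gaussian_blur(vals, smoothing_sigma) else vals
  basins <- matrix(.ws_flood_cpp(as.numeric(h), H, W), H, W)
  rm0 <- derive_regions(basins)
  # boundary re-derivation after a merge can leave new sub-threshold
  # fragments, so clean up to a fixed point (bounded)
  for (it in 1:5) {
    if (min_region_area <= 1 || rm0$n_regions <= 1) break
    sizes <- tabulate(rm0$labels[rm0$labels > 0], rm0$n_regions)
    if (all(sizes >= min_region_area)) break
    adj <- build_adjacency(rm0, contour_map(clamp(vals, 0, 1)), validate = FALSE)
    rm1 <- merge_small_regions(rm0, adj, min_region_area)
    if (identical(rm1$labels, rm0$labels)) break
    rm0 <- rm1
  }
  rm0
}

#' Region adjacency statistics
#'
#' For every boundary (0) pixel, the distinct region labels among its 4
#' neighbours define adjacent pairs; for each pair, `L` counts the shared
#' boundary pixels and `B` is the mean contour value over them.
#'
#' @param regions a `region_map`.
#' @param contour aligned `contour_map` (or matrix).
#' @param validate check region-map invariants first.
#' @return data.frame with columns `i`, `j` (`i < j`), `B`, `L`.
#' @export
build_adjacency <- function(regions, contour, validate = TRUE) {
  vals <- if (inherits(contour, "contour_map")) contour$values else contour
  labels <- regions$labels
  stopifnot(all(dim(labels) == dim(vals)))
  if (validate) validate_region_map(regions)
  H <- nrow(labels); W <- ncol(labels)
  zi <- which(labels == 0)
  if (length(zi) == 0)
    return(data.frame(i = integer(0), j = integer(0), B = numeric(0), L = integer(0)))
  y <- (zi - 1L) %% H + 1L
  x <- (zi - 1L) %/% H + 1L
  nb <- function(dy, dx) {
    yy <- y + dy; xx <- x + dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    out <- integer(length(zi))
    out[ok] <- labels[cbind(yy[ok], xx[ok])]
    out
  }
  NB <- cbind(nb(-1, 0), nb(1, 0), nb(0, -1), nb(0, 1))
  pr <- utils::combn(4, 2)
  recs <- vector("list", ncol(pr))
  for (q in seq_len(ncol(pr))) {
    a <- pmin(NB[, pr[1, q]], NB[, pr[2, q]])
    b <- pmax(NB[, pr[1, q]], NB[, pr[2, q]])
    ok <- a > 0 & a != b
    if (any(ok)) recs[[q]] <- data.frame(p = zi[ok], i = a[ok], j = b[ok])
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    return(data.frame(i = integer(0), j = integer(0), B = numeric(0), L = integer(0)))
  K <- max(recs$j) + 1
  pairkey <- recs$i * K + recs$j
  # one contribution per (pixel, pair); keys stay below 2^53 so exact
  dup <- duplicated(recs$p * (K * K) + pairkey)
  recs <- recs[!dup, , drop = FALSE]
  pairkey <- pairkey[!dup]
  Lagg <- rowsum(rep(1L, nrow(recs)), pairkey)
  Bagg <- rowsum(vals[recs$p], pairkey) / Lagg
  keys <- as.numeric(rownames(Lagg))
  out <- data.frame(i = as.integer(keys %/% K), j = as.integer(keys %% K),
                    B = as.numeric(Bagg), L = as.integer(Lagg))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- greedy merging (C++ engine) ------------------------------------------
#
# The union-find merge engine with length-weighted boundary strengths lives
# in src/merge.cpp; all tie-breaks use region ids, which are assigned in
# raster-scan order and therefore crop-consistent.

# rebuild a region map after merging: relabel the owner-resolved full
# raster through the union-find roots, then re-derive crack boundaries;
# boundaries interior to a merged region disappear because the labels on
# both sides coincide
rebuild_regions <- function(rm, roots) {
  if (all(roots == seq_along(roots))) return(rm)
  owners <- rm$owners
  if (is.null(owners)) owners <- fill_owners(rm)
  full <- matrix(roots[owners], nrow(rm$labels), ncol(rm$labels))
  derive_regions(full)
}

# owner fallback for region maps built directly from a labelled raster
# (e.g. in tests): resolve boundary pixels to the smallest adjacent region
fill_owners <- function(rm) {
  full <- rm$labels
  H <- nrow(full); W <- ncol(full)
  repeat {
    todo <- full == 0
    if (!any(todo)) break
    best <- matrix(.Machine$integer.max, H, W)
    for (d in list(c(-1, 0), c(0, -1), c(1, 0), c(0, 1))) {
      nb <- matrix(0L, H, W)
      ys <- seq_len(H) + d[1]; xs <- seq_len(W) + d[2]
      okY <- ys >= 1 & ys <= H; okX <- xs >= 1 & xs <= W
      nb[okY, okX] <- full[ys[okY], xs[okX]]
      upd <- todo & nb > 0 & nb < best
      best[upd] <- nb[upd]
    }
    got <- todo & best < .Machine$integer.max
    if (!any(got)) break
    full[got] <- best[got]
  }
  full
}

merge_small_regions <- function(rm, adjacency, min_area) {
  sizes <- tabulate(rm$labels[rm$labels > 0], rm$n_regions)
  roots <- .merge_small_cpp(rm$n_regions, as.integer(adjacency$i),
                            as.integer(adjacency$j),
                            as.numeric(adjacency$B), as.numeric(adjacency$L),
                            as.numeric(sizes), min_area)
  rebuild_regions(rm, roots)
}

#' Merge regions below a boundary-strength threshold
#'
#' Iteratively merges the adjacent pair with the minimum boundary strength
#' `B` while that minimum is below `ucm_threshold`, recomputing merged-edge
#' strengths as length-weighted means. Outputs at increasing thresholds are
#' nested partitions.
#'
#' @param regions a `region_map`.
#' @param adjacency output of [build_adjacency()].
#' @param ucm_threshold boundary-strength level in `[0, 1]` (or slightly
#'   above 1 to force a single region).
#' @return a coarser `region_map`.
#' @export
threshold_merge <- function(regions, adjacency, ucm_threshold) {
  stopifnot(ucm_threshold >= 0)
  res <- .merge_greedy_cpp(regions$n_regions, as.integer(adjacency$i),
                           as.integer(adjacency$j),
                           as.numeric(adjacency$B), as.numeric(adjacency$L),
                           ucm_threshold, TRUE)
  rebuild_regions(regions, res$roots)
}
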