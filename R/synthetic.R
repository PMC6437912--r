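# Synthetic H&E-like muscle images with exact ground truth.
#
# Muscle fibers in cross-section are convex, space-filling polygons separated
# by a thin, lighter interstitial band. The generator emulates this with a
# seeded Voronoi tessellation (one Lloyd relaxation step for realistic size
# uniformity), an interstitial band of controllable thickness and contrast,
# optional "broken" (faded) boundary arcs, per-cell stain jitter, Gaussian
# blur and additive pixel noise. The label raster is exact and unaffected by
# rendering noise.

#' Specification of a synthetic muscle image
#'
#' @param height,width image size in pixels (>= 64).
#' @param n_cells number of cells (>= 1).
#' @param boundary_thickness half-width of the interstitial band, pixels (>= 1).
#' @param boundary_contrast contrast of the band against cell colour, in
#'   `[0, 1]`; 0 makes boundaries invisible.
#' @param boundary_break_prob probability that the boundary arc between a
#'   given pair of adjacent cells is faded towards the cell colour.
#' @param cell_color_mean mean cell RGB colour, 3-vector in `[0, 255]`.
#' @param cell_color_std per-cell colour jitter standard deviation (0-255 scale).
#' @param noise_std additive pixel noise standard deviation (0-255 scale).
#' @param blur_sigma Gaussian blur applied to the rendered image, pixels.
#' @param seed integer seed; identical specs give bit-identical output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 512, width = 512, n_cells = 30,
                           boundary_thickness = 2, boundary_contrast = 0.7,
                           boundary_break_prob = 0.1,
                           cell_color_mean = c(205, 120, 140),
                           cell_color_std = 12, noise_std = 8,
                           blur_sigma = 1, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_cells = as.integer(n_cells),
               boundary_thickness = boundary_thickness,
               boundary_contrast = boundary_contrast,
               boundary_break_prob = boundary_break_prob,
               cell_color_mean = cell_color_mean,
               cell_color_std = cell_color_std, noise_std = noise_std,
               blur_sigma = blur_sigma, seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (height < 64 || width < 64)
      stop("synthetic image must be at least 64 x 64 pixels", call. = FALSE)
    if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
    if (boundary_thickness < 1) stop("boundary_thickness must be >= 1", call. = FALSE)
    if (boundary_contrast < 0 || boundary_contrast > 1)
      stop("boundary_contrast must be in [0, 1]", call. = FALSE)
    if (boundary_break_prob < 0 || boundary_break_prob > 1)
      stop("boundary_break_prob must be in [0, 1]", call. = FALSE)
    if (length(cell_color_mean) != 3 || any(cell_color_mean < 0) ||
        any(cell_color_mean > 255))
      stop("cell_color_mean must be a 3-vector in [0, 255]", call. = FALSE)
  })
  invisible(spec)
}

# For every pixel, squared distance and index of the two nearest seeds.
# Chunked over rows so 2000x2000 x several hundred seeds stays in memory.
nearest_two <- function(H, W, seeds, chunk = 262144L) {
  n <- H * W
  d1 <- rep(Inf, n); d2 <- rep(Inf, n)
  a1 <- integer(n); a2 <- integer(n)
  px <- rep(seq_len(W), each = H)
  py <- rep(seq_len(H), times = W)
  starts <- seq(1L, n, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, n)
    cy <- py[idx]; cx <- px[idx]
    cd1 <- d1[idx]; cd2 <- d2[idx]; ca1 <- a1[idx]; ca2 <- a2[idx]
    for (s in seq_len(nrow(seeds))) {
      d <- (cy - seeds[s, 1])^2 + (cx - seeds[s, 2])^2
      new1 <- d < cd1
      upd2 <- !new1 & (d < cd2)
      ca2[upd2] <- s; cd2[upd2] <- d[upd2]
      ca2[new1] <- ca1[new1]; cd2[new1] <- cd1[new1]
      ca1[new1] <- s; cd1[new1] <- d[new1]
    }
    d1[idx] <- cd1; d2[idx] <- cd2; a1[idx] <- ca1; a2[idx] <- ca2
  }
  list(d1 = d1, d2 = d2, a1 = a1, a2 = a2)
}

#' Generate a synthetic muscle image with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `image` (H x W x 3 array in `[0, 1]`) and `gt`, a
#'   `ground_truth` object: `labels` (integer matrix, 0 = interstitial
#'   band/background, k >= 1 = cell id) and `n_cells`.
#' @examples
#' out <- generate_image(synthetic_spec(n_cells = 10, height = 128, width = 128))
#' table(out$gt$labels == 0)
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  H <- spec$height; W <- spec$width; K <- spec$n_cells
  with_seed(spec$seed, {
    seeds <- cbind(runif(K, 1, H), runif(K, 1, W))
    # one Lloyd relaxation step: move each seed to its Voronoi cell centroid
    if (K > 1) {
      nt <- nearest_two(H, W, seeds)
      py <- rep(seq_len(H), times = W); px <- rep(seq_len(W), each = H)
      cy <- tapply(py, nt$a1, mean); cx <- tapply(px, nt$a1, mean)
      got <- as.integer(names(cy))
      seeds[got, 1] <- cy; seeds[got, 2] <- cx
      nt <- nearest_two(H, W, seeds)
    } else {
      nt <- list(d1 = rep(0, H * W), d2 = rep(Inf, H * W),
                 a1 = rep(1L, H * W), a2 = rep(0L, H * W))
    }
    labels <- matrix(nt$a1, H, W)
    margin <- (sqrt(nt$d2) - sqrt(nt$d1)) / 2
    band <- matrix(margin < spec$boundary_thickness, H, W)
    # image border is treated as boundary so every cell is band-enclosed
    bt <- ceiling(spec$boundary_thickness)
    border <- matrix(FALSE, H, W)
    border[c(seq_len(bt), H - seq_len(bt) + 1L), ] <- TRUE
    border[, c(seq_len(bt), W - seq_len(bt) + 1L)] <- TRUE
    gt_labels <- labels
    gt_labels[band | border] <- 0L

    present <- sort(unique(as.vector(gt_labels)))
    if (!identical(setdiff(present, 0L), seq_len(K)))
      stop("a cell was eroded away; reduce n_cells or boundary_thickness ",
           "for this image size", call. = FALSE)

    # rendering
    cols <- matrix(rep(spec$cell_color_mean, each = K), K, 3) +
      matrix(rnorm(3 * K, 0, spec$cell_color_std), K, 3)
    cols <- clamp(cols, 0, 255) / 255
    img <- array(0, c(H, W, 3))
    nearest <- as.vector(labels)
    # per-pair break draws, in sorted pair order for determinism
    pair_a <- pmin(nt$a1, nt$a2); pair_b <- pmax(nt$a1, nt$a2)
    bandv <- as.vector(band) & pair_b > 0
    keys <- sort(unique(pair_a[bandv] * (K + 1) + pair_b[bandv]))
    broken <- runif(length(keys)) < spec$boundary_break_prob
    fade_of <- rep(1, length(keys))
    fade_of[broken] <- runif(sum(broken), 0, 0.15)
    names(fade_of) <- as.character(keys)
    fade <- rep(1, H * W)
    fade[bandv] <- fade_of[as.character(pair_a[bandv] * (K + 1) + pair_b[bandv])]
    bnd <- as.vector(band | border)
    mixf <- ifelse(bnd, spec$boundary_contrast * fade, 0)
    for (c in 1:3) {
      base <- cols[nearest, c]
      img[, , c] <- matrix(base + mixf * (1 - base), H, W)
    }
    if (spec$blur_sigma > 0)
      for (c in 1:3) img[, , c] <- gaussian_blur(img[, , c], spec$blur_sigma)
    if (spec$noise_std > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_std / 255), dim(img))
    img <- clamp(img, 0, 1)
    gt <- structure(list(labels = gt_labels, n_cells = K), class = "ground_truth")
    list(image = img, gt = gt)
  })
}

#' Binary contour map of a ground-truth labelling
#'
#' A pixel is a contour pixel iff it is a background/interstitial pixel
#' (label 0) with at least one cell pixel among its 8 neighbours, i.e. it
#' lies on the interface between a cell and non-cell or between two cells.
#' This is the training target for the structured contour forest.
#'
#' @param gt a `ground_truth` object or an integer label matrix.
#' @return integer matrix of 0/1.
#' @export
boundary_map <- function(gt) {
  labels <- if (inherits(gt, "ground_truth")) gt$labels else gt
  stopifnot(is.matrix(labels))
  H <- nrow(labels); W <- ncol(labels)
  nz <- labels > 0
  any_cell <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- clamp(seq_len(H) + dy, 1L, H); xs <- clamp(seq_len(W) + dx, 1L, W)
    any_cell <- any_cell | nz[ys, xs]
  }
  out <- matrix(0L, H, W)
  out[!nz & any_cell] <- 1L
  out
}

# 2-D summed-area table lookup of window sums (side s), top-left (y0, x0) 1-based
window_sums <- function(m, s) {
  S <- apply(apply(m, 2, cumsum), 1, cumsum) # S[x, y] transposed
  S <- t(S)
  Sp <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  Sp[-1, -1] <- S
  H <- nrow(m) - s + 1; W <- ncol(m) - s + 1
  y <- seq_len(H); x <- seq_len(W)
  Sp[y + s, x + s, drop = FALSE] - Sp[y, x + s, drop = FALSE] -
    Sp[y + s, x, drop = FALSE] + Sp[y, x, drop = FALSE]
}

#' Sample training patches for the structured contour forest
#'
#' Samples `n` patch positions, stratified so that at least a quarter of
#' them contain a contour pixel in the central `d_out` x `d_out` label
#' window (when the image has any contour at all). Features are the
#' [compute_channels()] stack over the enclosing `d_in` window.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param gt ground truth (see [boundary_map()]).
#' @param d_in,d_out feature and label window sides, even, `d_out <= d_in`.
#' @param n number of patches.
#' @param seed integer seed.
#' @param channels optional precomputed [compute_channels()] stack.
#' @return object of class `patch_samples`: list with `X` (n x d_in^2*13
#'   feature matrix, layout y-fastest then x then channel), `Y` (n x d_out^2
#'   binary label matrix), `coords`, `d_in`, `d_out`.
#' @export
sample_patches <- function(image, gt, d_in = 32, d_out = 16, n = 500,
                           seed = 1L, channels = NULL) {
  stopifnot(d_out <= d_in, d_in %% 2 == 0, d_out %% 2 == 0, n >= 1)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < d_in || W < d_in) stop("image smaller than d_in", call. = FALSE)
  if (is.null(channels)) channels <- compute_channels(image)
  bmap <- boundary_map(gt)
  off <- (d_in - d_out) / 2
  # centre-window top-left candidates with the full d_in window in bounds
  ws <- window_sums(bmap, d_out)
  ys <- (off + 1):(H - d_out - off + 1)
  xs <- (off + 1):(W - d_out - off + 1)
  pos_mask <- ws[ys, xs, drop = FALSE] > 0
  cand <- expand.grid(cy = ys, cx = xs)
  pos_idx <- which(as.vector(pos_mask))
  with_seed(seed, {
    n_pos <- min(length(pos_idx), ceiling(n / 2))
    take_pos <- if (n_pos > 0) pos_idx[sample.int(length(pos_idx), n_pos)] else integer(0)
    take_any <- sample.int(nrow(cand), n - n_pos)
    take <- c(take_pos, take_any)
    X <- matrix(0, n, d_in * d_in * 13)
    Y <- matrix(0L, n, d_out * d_out)
    for (i in seq_len(n)) {
      cy <- cand$cy[take[i]]; cx <- cand$cx[take[i]]
      y0 <- cy - off; x0 <- cx - off
      X[i, ] <- as.vector(channels$values[y0:(y0 + d_in - 1),
                                          x0:(x0 + d_in - 1), ])
      Y[i, ] <- as.integer(bmap[cy:(cy + d_out - 1), cx:(cx + d_out - 1)])
    }
    structure(list(X = X, Y = Y,
                   coords = cbind(cy = cand$cy[take], cx = cand$cx[take]),
                   d_in = d_in, d_out = d_out),
              class = "patch_samples")
  })
}

# sparse intersection counts between two label rasters (zeros excluded)
intersection_counts <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  keep <- av > 0 & bv > 0
  if (!any(keep)) return(data.frame(i = integer(0), j = integer(0), n = integer(0)))
  key <- av[keep] * (max(bv) + 1) + bv[keep]
  tab <- table(key)
  k <- as.numeric(names(tab))
  data.frame(i = as.integer(k %/% (max(bv) + 1)),
             j = as.integer(k %% (max(bv) + 1)),
             n = as.integer(tab))
}

#' Build a region-scoring training set from a candidate region map
#'
#' Labels every base region of `region_map` positive iff its best
#' intersection-over-union with any ground-truth cell reaches `iou_pos`,
#' and pairs the label with the region's [region_features()] vector.
#'
#' @param region_map a `region_map` (see [oversegment()]).
#' @param gt ground truth aligned with the region map.
#' @param image RGB image the regions came from.
#' @param contour contour map aligned with the regions.
#' @param iou_pos IoU threshold for a positive example (default 0.7).
#' @param channels optional precomputed channel stack.
#' @return list with `features` (matrix), `label` (0/1 integer vector),
#'   `iou` (best IoU per region).
#' @export
sample_region_training_set <- function(region_map, gt, image, contour,
                                       iou_pos = 0.7, channels = NULL) {
  labels <- region_map$labels
  gl <- if (inherits(gt, "ground_truth")) gt$labels else gt
  stopifnot(all(dim(labels) == dim(gl)))
  if (region_map$n_regions < 1) stop("empty region map", call. = FALSE)
  if (is.null(channels)) channels <- compute_channels(image)
  ic <- intersection_counts(labels, gl)
  areas_r <- tabulate(labels[labels > 0], region_map$n_regions)
  areas_g <- tabulate(gl[gl > 0])
  best <- rep(0, region_map$n_regions)
  if (nrow(ic) > 0) {
    iou <- ic$n / (areas_r[ic$i] + areas_g[ic$j] - ic$n)
    agg <- tapply(iou, ic$i, max)
    best[as.integer(names(agg))] <- agg
  }
  px <- region_pixels(labels)
  buf <- new.env(parent = emptyenv())
  buf$mask <- logical(length(labels))
  feats <- t(vapply(seq_len(region_map$n_regions), function(r) {
    region_features_impl(px[[as.character(r)]], channels, contour,
                         nrow(labels), ncol(labels), buf)
  }, numeric(length(REGION_FEATURE_NAMES))))
  colnames(feats) <- REGION_FEATURE_NAMES
  list(features = feats, label = as.integer(best >= iou_pos), iou = best)
}
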