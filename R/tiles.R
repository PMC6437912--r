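# Tile-based processing of large images: partially overlapping tiles are
# segmented independently (an in-process worker pool plays the role of the
# distributed master-worker scheme) and stitched deterministically. Each
# tile keeps the cells whose centroid falls in its core; cores partition the
# image, so every cell has exactly one owner and the stitched result is
# independent of worker count and completion order.

#' Split an image into padded tiles
#'
#' Cores form a `ceiling(h / tile_size)` x `ceiling(w / tile_size)` grid of
#' disjoint rectangles covering the image; each padded rectangle expands the
#' core by `pad` pixels per side, clipped at the borders. Coordinates are
#' 0-based half-open `(y0, y1, x0, x1)`.
#'
#' @param image_h,image_w image size in pixels.
#' @param tile_size core side length (>= 64).
#' @param pad overlap padding per side (default 300, chosen to exceed any
#'   plausible cell diameter).
#' @return list of tile specs: `row`, `col`, `core`, `padded`.
#' @export
split_tiles <- function(image_h, image_w, tile_size = 1024, pad = 300) {
  if (image_h <= 0 || image_w <= 0) stop("image dimensions must be positive",
                                         call. = FALSE)
  stopifnot(tile_size >= 64, pad >= 0)
  nr <- ceiling(image_h / tile_size)
  nc <- ceiling(image_w / tile_size)
  tiles <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    y0 <- (r - 1) * tile_size; y1 <- min(r * tile_size, image_h)
    x0 <- (c - 1) * tile_size; x1 <- min(c * tile_size, image_w)
    tiles[[length(tiles) + 1L]] <- list(
      row = r, col = c,
      core = c(y0 = y0, y1 = y1, x0 = x0, x1 = x1),
      padded = c(y0 = max(0, y0 - pad), y1 = min(image_h, y1 + pad),
                 x0 = max(0, x0 - pad), x1 = min(image_w, x1 + pad)))
  }
  tiles
}

#' Segment one padded tile
#'
#' Runs the full single-image pipeline on the tile's padded crop with the
#' contour-voting grid aligned to global coordinates, so a tile reproduces
#' the standalone segmentation everywhere far enough from its padded border.
#'
#' @param image the full image (the crop is taken here).
#' @param tile a tile spec from [split_tiles()].
#' @param models a `muscleseg_models` object.
#' @param config optional config override.
#' @return list with `tile`, `labels` (padded-local raster), `cells`.
#' @export
process_tile <- function(image, tile, models, config = NULL) {
  p <- tile$padded
  crop <- image[(p["y0"] + 1):p["y1"], (p["x0"] + 1):p["x1"], , drop = FALSE]
  res <- segment_cells(crop, models, config,
                       origin = c(p[["y0"]], p[["x0"]]))
  list(tile = tile, labels = res$labels, cells = res$cells)
}

#' Stitch tile results into a full segmentation
#'
#' A cell is kept iff its centroid lies in its tile's core. Kept cells from
#' different tiles with mask IoU > 0.5 are duplicates of one physical cell:
#' the copy whose centroid lies deeper inside its core survives (tile order
#' on ties). Remaining partial overlaps resolve in favour of the
#' earlier-kept cell. Surviving cells are renumbered in (tile, cell) order.
#'
#' @param results list of [process_tile()] outputs covering all tiles.
#' @param image_h,image_w output raster size.
#' @return list with `labels` and `cells` (`cell`, `score`, `area`).
#' @export
stitch <- function(results, image_h, image_w) {
  if (length(results) == 0) stop("no tile results", call. = FALSE)
  got <- t(vapply(results, function(r) c(r$tile$row, r$tile$col), numeric(2)))
  for (r in seq_len(max(got[, 1]))) for (c in seq_len(max(got[, 2])))
    if (!any(got[, 1] == r & got[, 2] == c))
      stop(sprintf("missing tile (%d, %d)", r, c), call. = FALSE)
  out <- matrix(0L, image_h, image_w)
  kept <- list() # per kept cell: pixels (global), depth, score, area
  for (res in results) {
    t <- res$tile
    lab <- res$labels
    Hc <- nrow(lab); Wc <- ncol(lab)
    p <- t$padded; core <- t$core
    for (r in seq_len(nrow(res$cells))) {
      id <- res$cells$cell[r]
      px <- which(lab == id)
      ly <- (px - 1L) %% Hc # 0-based local
      lx <- (px - 1L) %/% Hc
      gy <- ly + p[["y0"]]; gx <- lx + p[["x0"]]
      cy <- mean(gy); cx <- mean(gx)
      inside <- cy >= core["y0"] && cy < core["y1"] &&
        cx >= core["x0"] && cx < core["x1"]
      if (!inside) next
      depth <- min(cy - core["y0"], core["y1"] - cy,
                   cx - core["x0"], core["x1"] - cx)
      gpx <- gx * image_h + gy + 1L # global column-major indices
      # duplicate check against already-kept cells
      hit <- unique(out[gpx])
      hit <- hit[hit > 0]
      dup <- FALSE
      for (h in hit) {
        inter <- sum(out[gpx] == h)
        iou <- inter / (length(gpx) + length(kept[[h]]$pixels) - inter)
        if (iou > 0.5) {
          if (depth > kept[[h]]$depth) {
            out[kept[[h]]$pixels] <- 0L # replace the shallower copy
            kept[[h]]$pixels <- integer(0)
          } else dup <- TRUE
        }
      }
      if (dup) next
      free <- gpx[out[gpx] == 0L]
      nid <- length(kept) + 1L
      out[free] <- nid
      kept[[nid]] <- list(pixels = free, depth = depth,
                          score = res$cells$score[r], area = length(free))
    }
  }
  alive <- which(vapply(kept, function(k) length(k$pixels) > 0, TRUE))
  map <- integer(length(kept))
  map[alive] <- seq_along(alive)
  nz <- out > 0
  out[nz] <- map[out[nz]]
  cells <- data.frame(cell = seq_along(alive),
                      score = vapply(alive, function(i) kept[[i]]$score, 1),
                      area = vapply(alive, function(i) kept[[i]]$area, 1))
  list(labels = out, cells = cells)
}

#' Tile-parallel segmentation of a large image
#'
#' Splits the image into padded tiles, segments them concurrently on an
#' in-process worker pool, and stitches the masked per-tile results. The
#' output is identical for every `n_workers` (scheduling invariance).
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param models a `muscleseg_models` object.
#' @param config optional config override (supplies `tile_size` and `pad`).
#' @param n_workers concurrent tile workers (>= 1).
#' @return as [stitch()].
#' @export
run_parallel <- function(image, models, config = NULL, n_workers = NULL) {
  cfg <- if (is.null(config)) models$config else config
  if (is.null(n_workers)) n_workers <- cfg$n_workers
  stopifnot(n_workers >= 1)
  H <- dim(image)[1]; W <- dim(image)[2]
  tiles <- split_tiles(H, W, cfg$tile_size, cfg$pad)
  worker <- function(i) {
    tryCatch(process_tile(image, tiles[[i]], models, cfg),
             error = function(e) {
               structure(list(tile = tiles[[i]], message = conditionMessage(e)),
                         class = "tile_error")
             })
  }
  results <- if (n_workers == 1) lapply(seq_along(tiles), worker)
  else parallel::mclapply(seq_along(tiles), worker, mc.cores = n_workers)
  for (r in results) {
    if (inherits(r, "tile_error") || inherits(r, "try-error"))
      stop(sprintf("tile (%d, %d) failed: %s", r$tile$row, r$tile$col,
                   r$message), call. = FALSE)
  }
  stitch(results, H, W)
}
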