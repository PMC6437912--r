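# Object-level (cell-wise) segmentation evaluation: greedy one-to-one
# matching by intersection area, per-cell precision/recall/F1, and the
# image-level averages with an explicit unmatched-cell penalty convention.

#' Match segmented cells to ground-truth cells
#'
#' Greedy one-to-one matching by descending intersection area (ties broken
#' by smaller id pair); pairs with zero intersection are never matched.
#'
#' @param seg,gt aligned integer label rasters (0 = background).
#' @return data.frame with `seg_id`, `gt_id`, `intersection`, `seg_area`,
#'   `gt_area`; each id appears at most once.
#' @export
match_cells <- function(seg, gt) {
  if (inherits(gt, "ground_truth")) gt <- gt$labels
  if (!all(dim(seg) == dim(gt))) stop("raster shapes differ", call. = FALSE)
  ic <- intersection_counts(seg, gt)
  empty <- data.frame(seg_id = integer(0), gt_id = integer(0),
                      intersection = integer(0), seg_area = integer(0),
                      gt_area = integer(0))
  if (nrow(ic) == 0) return(empty)
  areas_s <- tabulate(seg[seg > 0])
  areas_g <- tabulate(gt[gt > 0])
  ic <- ic[order(-ic$n, ic$i, ic$j), , drop = FALSE]
  used_s <- used_g <- integer(0)
  keep <- logical(nrow(ic))
  for (r in seq_len(nrow(ic))) {
    if (ic$i[r] %in% used_s || ic$j[r] %in% used_g) next
    keep[r] <- TRUE
    used_s <- c(used_s, ic$i[r]); used_g <- c(used_g, ic$j[r])
  }
  m <- ic[keep, , drop = FALSE]
  data.frame(seg_id = m$i, gt_id = m$j, intersection = m$n,
             seg_area = areas_s[m$i], gt_area = areas_g[m$j])
}

#' Precision, recall and F1 of one cell pair
#'
#' \eqn{P = |S \cap G| / |S|}, \eqn{R = |S \cap G| / |G|},
#' \eqn{F_1 = 2PR / (P + R)} (0 when both are 0).
#'
#' @param intersection overlap area `|S intersect G|`.
#' @param s_area,g_area areas of the segmented and ground-truth cell (> 0).
#' @return named vector `(precision, recall, f1)`.
#' @export
cell_prf <- function(intersection, s_area, g_area) {
  if (s_area <= 0 || g_area <= 0) stop("cell areas must be positive", call. = FALSE)
  if (intersection > min(s_area, g_area))
    stop("intersection exceeds a cell area", call. = FALSE)
  p <- intersection / s_area
  r <- intersection / g_area
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Image-level cell-wise metrics
#'
#' Per-cell precision/recall/F1 averaged over cells. Unmatched segmented
#' cells contribute precision 0, unmatched ground-truth cells contribute
#' recall 0, and both contribute F1 = 0, so the averages penalise false
#' positives and misses: the precision average divides by `n_seg`, the
#' recall average by `n_gt`, the F1 average by `max(n_seg, n_gt)`. Set
#' `penalize_unmatched = FALSE` to average over matched cells only.
#'
#' @param matches output of [match_cells()].
#' @param n_seg,n_gt numbers of segmented and ground-truth cells.
#' @param penalize_unmatched include unmatched cells in the averages.
#' @return named vector `(precision, recall, f1, n_matched)`.
#' @export
image_metrics <- function(matches, n_seg, n_gt, penalize_unmatched = TRUE) {
  if (n_seg == 0 && n_gt == 0)
    stop("no cells in either raster: metrics undefined", call. = FALSE)
  if (nrow(matches) == 0) {
    prf <- matrix(numeric(0), 0, 3)
  } else {
    prf <- t(mapply(cell_prf, matches$intersection, matches$seg_area,
                    matches$gt_area))
  }
  nm <- nrow(matches)
  if (penalize_unmatched) {
    p <- if (n_seg > 0) sum(prf[, 1]) / n_seg else 0
    r <- if (n_gt > 0) sum(prf[, 2]) / n_gt else 0
    f <- sum(prf[, 3]) / max(n_seg, n_gt)
  } else {
    p <- if (nm > 0) mean(prf[, 1]) else 0
    r <- if (nm > 0) mean(prf[, 2]) else 0
    f <- if (nm > 0) mean(prf[, 3]) else 0
  }
  c(precision = p, recall = r, f1 = f, n_matched = nm)
}

#' Precision-recall sweep over the cell score threshold
#'
#' Re-filters a segmentation by the per-cell classifier score: at each
#' threshold only cells whose node score reaches it are kept, and the
#' cell-wise metrics are recomputed against the ground truth.
#'
#' @param seg_result a pipeline result with `labels` and a `cells` table
#'   containing a `score` column (see [segment_cells()]).
#' @param gt ground-truth labels.
#' @param thresholds ascending score thresholds in `[0, 1]`.
#' @param penalize_unmatched passed to [image_metrics()].
#' @return data.frame with `threshold`, `precision`, `recall`, `f1`,
#'   `n_cells`.
#' @export
pr_curve <- function(seg_result, gt, thresholds = c(seq(0, 0.9, 0.1), 0.26),
                     penalize_unmatched = TRUE) {
  thresholds <- sort(unique(thresholds))
  stopifnot(all(thresholds >= 0))
  if (inherits(gt, "ground_truth")) gt <- gt$labels
  n_gt <- length(setdiff(unique(as.vector(gt)), 0L))
  rows <- lapply(thresholds, function(th) {
    keep <- seg_result$cells$cell[seg_result$cells$score >= th]
    lab <- seg_result$labels
    lab[!(lab %in% keep)] <- 0L
    n_seg <- length(keep)
    if (n_seg == 0 && n_gt == 0) {
      m <- c(precision = NA, recall = NA, f1 = NA, n_matched = 0)
    } else if (n_seg == 0) {
      m <- c(precision = 0, recall = 0, f1 = 0, n_matched = 0)
    } else {
      m <- image_metrics(match_cells(lab, gt), n_seg, n_gt,
                         penalize_unmatched)
    }
    data.frame(threshold = th, precision = m[["precision"]],
               recall = m[["recall"]], f1 = m[["f1"]], n_cells = n_seg)
  })
  do.call(rbind, rows)
}
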