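# End-to-end pipeline: configuration, model training, and single-image
# segmentation (contours -> region candidates -> tree -> CRF selection).

#' Pipeline configuration
#'
#' All tunables of the segmentation pipeline with their defaults.
#'
#' @param n_trees,d_in,d_out,stride,max_depth,min_samples_leaf,sample_frac,feature_frac
#'   structured-forest parameters (see [forest_params()] and
#'   [predict_contours()]).
#' @param n_patches training patches sampled per training image.
#' @param smoothing_sigma,min_region_area watershed parameters
#'   ([oversegment()]).
#' @param ucm_threshold boundary-strength threshold for coarse candidate
#'   maps ([threshold_merge()]).
#' @param mu,epsilon CRF energy constants ([energy_model()]).
#' @param cut_threshold contour strength above which adjacent regions are
#'   treated as separate cells ([cut_tree()]).
#' @param max_exhaustive_leaves largest subtree solved by enumeration;
#'   larger subtrees use [infer_fast()].
#' @param score_threshold minimum classifier score for a selected cell to be
#'   kept (the operating point of the precision-recall sweep).
#' @param iou_pos IoU threshold labelling a training region positive.
#' @param tile_size,pad,n_workers tiling parameters ([run_parallel()]).
#' @param seed base seed for all seeded stages.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_trees = 8, d_in = 32, d_out = 16, stride = 8,
                            max_depth = 32, min_samples_leaf = 8,
                            sample_frac = 0.5, feature_frac = 0.25,
                            n_patches = 600,
                            smoothing_sigma = 1, min_region_area = 30,
                            ucm_threshold = 0.5,
                            mu = 0.005, epsilon = 1e-6, cut_threshold = 0.2,
                            max_exhaustive_leaves = 12,
                            score_threshold = 0.26, iou_pos = 0.7,
                            tile_size = 1024, pad = 300, n_workers = 1,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

config_forest_params <- function(cfg) {
  forest_params(n_trees = cfg$n_trees, sample_frac = cfg$sample_frac,
                feature_frac = cfg$feature_frac, max_depth = cfg$max_depth,
                min_samples_leaf = cfg$min_samples_leaf, seed = cfg$seed)
}

# node-level scorer training set from one training image
node_training_set <- function(tree, regions, gt, channels, contour, iou_pos) {
  labels <- regions$labels
  gl <- if (inherits(gt, "ground_truth")) gt$labels else gt
  px <- node_pixels(tree, labels)
  feats <- node_feature_matrix(tree, labels, channels, contour,
                               leaf_stats(labels, channels, contour))
  # leaf/GT intersections, aggregated up the tree
  ic <- intersection_counts(labels, gl)
  areas_g <- tabulate(gl[gl > 0])
  ng <- length(areas_g)
  inter <- matrix(0, tree$n_nodes, ng)
  if (nrow(ic) > 0) {
    leaf_of <- match(ic$i, tree$leaf_regions)
    ok <- !is.na(leaf_of)
    inter[cbind(leaf_of[ok], ic$j[ok])] <- ic$n[ok]
  }
  area_n <- vapply(px, length, 1L)
  if (tree$n_nodes > tree$n_leaves)
    for (i in (tree$n_leaves + 1):tree$n_nodes)
      inter[i, ] <- inter[tree$left[i], ] + inter[tree$right[i], ]
  iou <- inter / (outer(area_n, rep(1, ng)) +
                  outer(rep(1, tree$n_nodes), areas_g) - inter)
  best <- if (ng > 0) apply(iou, 1, max) else rep(0, tree$n_nodes)
  list(features = feats, label = as.integer(best >= iou_pos), iou = best)
}

#' Build a region-scorer training set from one annotated image
#'
#' Runs the candidate-generation front end (contour prediction, watershed,
#' merge tree) and labels every tree node by its best IoU against the
#' ground-truth cells, so the scorer sees both over-segmented fragments
#' (negatives) and correctly merged cell regions (positives).
#'
#' @param image RGB array in `[0, 1]`.
#' @param gt aligned ground truth.
#' @param forest trained `forest_model`.
#' @param config a [pipeline_config()].
#' @param channels optional precomputed channel stack.
#' @return list with `features`, `label`, `iou`.
#' @export
scorer_training_set <- function(image, gt, forest, config = pipeline_config(),
                                channels = NULL) {
  if (is.null(channels)) channels <- compute_channels(image)
  contour <- predict_contours(channels, forest, stride = config$stride)
  regions <- oversegment(contour, config$smoothing_sigma,
                         config$min_region_area)
  adjacency <- build_adjacency(regions, contour, validate = FALSE)
  tree <- build_tree(regions, adjacency)
  node_training_set(tree, regions, gt, channels, contour, config$iou_pos)
}

#' Train the contour forest and region scorer
#'
#' Trains the structured contour forest on patches pooled over the training
#' images, then runs the candidate-generation front end on each training
#' image and labels every merge-tree node by its best IoU against the
#' ground truth to train the region-scoring classifier.
#'
#' @param train_data list of `list(image, gt)` pairs (e.g. from
#'   [generate_image()]).
#' @param config a [pipeline_config()].
#' @return list of class `muscleseg_models` with `forest`, `scorer`,
#'   `config`.
#' @export
train_segmentation_models <- function(train_data, config = pipeline_config()) {
  stopifnot(length(train_data) >= 1)
  chans <- lapply(train_data, function(d) compute_channels(d$image))
  samp <- lapply(seq_along(train_data), function(i) {
    sample_patches(train_data[[i]]$image, train_data[[i]]$gt,
                   d_in = config$d_in, d_out = config$d_out,
                   n = config$n_patches, seed = mix_seed(config$seed, i),
                   channels = chans[[i]])
  })
  pooled <- list(X = do.call(rbind, lapply(samp, `[[`, "X")),
                 Y = do.call(rbind, lapply(samp, `[[`, "Y")),
                 d_in = config$d_in, d_out = config$d_out)
  forest <- train_forest(pooled, config_forest_params(config))

  sets <- lapply(seq_along(train_data), function(i) {
    scorer_training_set(train_data[[i]]$image, train_data[[i]]$gt, forest,
                        config, channels = chans[[i]])
  })
  feats <- do.call(rbind, lapply(sets, `[[`, "features"))
  labs <- unlist(lapply(sets, `[[`, "label"))
  scorer <- train_region_scorer(feats, labs, seed = config$seed)
  structure(list(forest = forest, scorer = scorer, config = config,
                 version = 1L),
            class = "muscleseg_models")
}

#' @export
print.muscleseg_models <- function(x, ...) {
  cat("<muscleseg_models>\n")
  print(x$forest)
  invisible(x)
}

#' Segment muscle cells in one image
#'
#' Runs the full pipeline: contour prediction, watershed region candidates,
#' merge-tree construction, contour-threshold tree cutting, node scoring and
#' CRF inference per subtree (exhaustive when small, dynamic program plus
#' local search otherwise), and assembly of the selected cells. Cells whose
#' classifier score falls below `config$score_threshold` are discarded.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param models a `muscleseg_models` object.
#' @param config optional [pipeline_config()] override (defaults to the
#'   one the models were trained with).
#' @param origin global (y, x) 0-based offset of the image crop, used to
#'   keep the contour-voting grid aligned when processing tiles.
#' @param n_workers workers for contour-prediction chunking.
#' @return list with `labels` (cell raster), `cells` (data.frame `cell`,
#'   `score`, `area`), `contour`, `regions`.
#' @export
segment_cells <- function(image, models, config = NULL, origin = c(0L, 0L),
                          n_workers = 1) {
  stopifnot(inherits(models, "muscleseg_models"))
  cfg <- if (is.null(config)) models$config else config
  channels <- compute_channels(image)
  contour <- predict_contours(channels, models$forest, stride = cfg$stride,
                              n_workers = n_workers, origin = origin)
  regions <- oversegment(contour, cfg$smoothing_sigma, cfg$min_region_area)
  adjacency <- build_adjacency(regions, contour, validate = FALSE)
  tree <- build_tree(regions, adjacency)
  subtrees <- cut_tree(tree, adjacency, cfg$cut_threshold)
  H <- nrow(regions$labels); W <- ncol(regions$labels)

  labelings <- vector("list", length(subtrees))
  scores_by_tree <- vector("list", length(subtrees))
  lstats <- leaf_stats(regions$labels, channels, contour)
  for (t in seq_along(subtrees)) {
    tr <- subtrees[[t]]
    s <- score_nodes(tr, models$scorer, regions$labels, channels, contour,
                     lstats)
    scores_by_tree[[t]] <- s
    keep <- adjacency$i %in% tr$leaf_regions & adjacency$j %in% tr$leaf_regions
    edges <- data.frame(li = match(adjacency$i[keep], tr$leaf_regions),
                        lj = match(adjacency$j[keep], tr$leaf_regions),
                        B = adjacency$B[keep], L = adjacency$L[keep])
    em <- energy_model(s, edges, mu = cfg$mu, epsilon = cfg$epsilon)
    labelings[[t]] <- if (tr$n_leaves <= cfg$max_exhaustive_leaves)
      infer_exact(tr, em, max_leaves = cfg$max_exhaustive_leaves)
    else infer_fast(tr, em)
  }
  seg <- select_segments(subtrees, labelings, regions)
  cells <- seg$cells
  if (nrow(cells) > 0) {
    cells$score <- mapply(function(t, nd) scores_by_tree[[t]][nd],
                          cells$subtree, cells$node)
    drop <- cells$cell[cells$score < cfg$score_threshold]
    if (length(drop) > 0) {
      seg$labels[seg$labels %in% drop] <- 0L
      cells <- cells[!(cells$cell %in% drop), , drop = FALSE]
    }
    # renumber surviving cells 1..K
    if (nrow(cells) > 0) {
      new_id <- seq_len(nrow(cells))
      map <- integer(max(seg$labels, 1L))
      map[cells$cell] <- new_id
      nz <- seg$labels > 0
      seg$labels[nz] <- map[seg$labels[nz]]
      cells$cell <- new_id
    }
  } else {
    cells$score <- numeric(0)
  }
  rownames(cells) <- NULL
  list(labels = seg$labels, cells = cells[, c("cell", "score", "area")],
       contour = contour, regions = regions)
}
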