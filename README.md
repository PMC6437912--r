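# muscleseg

Segmentation of individual skeletal muscle fibers in H&E-stained
microscopy images. Muscle cross-sections show hundreds to thousands of
densely packed, convex fibers separated by thin, often faint interstitial
boundaries; downstream morphometry (fiber size, shape, type grouping)
needs every fiber delineated individually, which makes hand annotation
impractical and demands a segmentation method that is robust to broken
contours and fast enough for tiled, parallel processing of large scans.

The pipeline:

1. **Structured random forest (SRF) contour detection.** Each decision
   tree maps a 32×32×13 feature window (CIE-Lab, gradient magnitude at two
   blur scales, oriented gradient energy at four orientations × two
   scales) to a 16×16 *binary contour patch* at its leaf; structured
   labels are made splittable by mapping them to discrete classes at every
   node (pairwise pixel comparisons projected on their first principal
   direction) and scoring splits with Gini information gain,
   `C = H(D) − Σ_o (|D_o|/|D|) H(D_o)`. Averaging all overlapping leaf
   votes yields a contour probability map.
2. **Region candidates.** A deterministic watershed transform of the
   contour map produces an over-segmentation into base regions with
   closed, single-pixel-wide boundaries; each adjacent pair carries a
   boundary strength `B` (mean contour value on the shared boundary) and
   length `L`.
3. **Hierarchical CRF region selection.** The `N` base regions are
   agglomerated weakest-boundary-first into a binary merge tree with
   `2N−1` nodes; a random-forest region scorer assigns every node a cell
   probability `s_i`, and the selected cells minimise

   ```
   E = Σ_i U_i + Σ_(i,j) μ · exp(−B_ij) · L_ij
   U_i = −log(s_i + ε)        if node i is selected
       = −log(1 − s_i + ε)    otherwise
   ```

   under the non-overlap (antichain) constraint — no selected node is an
   ancestor of another. Strong contours cut the tree into independent
   subtrees first, so inference is exact (full antichain enumeration) on
   small subtrees and a dynamic program plus local search on large ones.
4. **Tile-parallel processing.** Large images are split into padded,
   partially overlapping tiles (default padding 300 px), segmented
   concurrently on an in-process worker pool, and stitched by centroid
   ownership with IoU de-duplication. The stitched result is *exactly*
   equal to the standalone segmentation and independent of the worker
   count.

Because no imaging data ships with the package, a synthetic generator
(`generate_image()`) produces H&E-like muscle images — Lloyd-relaxed
Voronoi cells, controllable boundary contrast and breaks, stain jitter and
noise — with exact ground-truth labels, and the evaluation module scores
segmentations cell-wise (greedy one-to-one matching; per-cell precision,
recall and F1 averaged with explicit penalties for misses and false
positives).

## Worked example

Train on two synthetic images, segment a held-out one, evaluate:

```r
library(muscleseg)

spec <- function(seed) synthetic_spec(n_cells = 30, height = 512, width = 512,
                                      boundary_contrast = 0.5,
                                      boundary_break_prob = 0, seed = seed)
train  <- list(generate_image(spec(101)), generate_image(spec(102)))
models <- train_segmentation_models(train, pipeline_config())

test <- generate_image(spec(103))
res  <- segment_cells(test$image, models)
nrow(res$cells)                       # number of segmented cells
m <- image_metrics(match_cells(res$labels, test$gt),
                   nrow(res$cells), test$gt$n_cells)
round(m, 3)
```

```
#> [1] 30
#> precision    recall        f1 n_matched
#>     0.920     0.971     0.944    30.000
```

All 30 ground-truth fibers are recovered (`n_matched = 30`, recall 0.97);
precision 0.92 mostly reflects the one-pixel boundary-band dilation of the
segmented masks relative to the eroded ground-truth cells, and the mean
per-cell F1 of 0.94 is the headline quality number on these study
conditions. On a
1200×1200, 100-cell image, `run_parallel(image, models, cfg, n_workers = 4)`
returns a raster identical (after renumbering) to `segment_cells()` for
any worker count.

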