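---
title: "Segmenting skeletal muscle fibers with structured forests and a hierarchical CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting skeletal muscle fibers with structured forests and a hierarchical CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleseg)
```

## The problem

Cross-sections of H&E-stained skeletal muscle show densely packed, roughly
convex fibers separated by a thin, lighter interstitial band. Quantifying
fiber size and shape requires segmenting every individual fiber, and
whole-slide scans contain hundreds to thousands of them, so the
segmentation must be both accurate on low-contrast, partially broken
boundaries and fast enough to run tiled and in parallel.

`muscleseg` implements a four-stage pipeline:

1. **Contour detection** with a structured random forest (SRF): each tree
   maps a $d_\mathrm{in} \times d_\mathrm{in} \times 13$ feature window to
   a $d_\mathrm{out} \times d_\mathrm{out}$ *binary contour patch* stored
   at its leaf; averaging all overlapping patch votes gives a per-pixel
   contour probability map.
2. **Region candidates** by a watershed transform of the contour map:
   an over-segmentation into base regions $R_1,\dots,R_N$ with closed,
   single-pixel-wide boundaries, plus the adjacency statistics
   $B(R_i,R_j)$ (mean contour strength on the shared boundary) and
   $L(R_i,R_j)$ (its length).
3. **Hierarchical region selection**: the base regions are agglomerated
   (weakest boundary first) into a binary merge tree with $2N-1$ nodes.
   Every node is a candidate cell and is scored by a random-forest
   classifier on 14 shape/appearance features. Final cells minimise the
   CRF energy
   $$E = \sum_{i=1}^{2N-1} U_i + \sum_{(i,j)} \mu\, e^{-B_{ij}} L_{ij},$$
   with $U_i = -\log(s_i+\varepsilon)$ for selected nodes and
   $-\log(1-s_i+\varepsilon)$ otherwise, subject to the *antichain*
   constraint: no selected node may be an ancestor of another, so cells
   never overlap. The pairwise term fires when two adjacent base regions
   end up with different cell labels, so weak boundaries (small $B$, large
   penalty) discourage splitting.
4. **Tiling**: large images are cut into partially overlapping tiles,
   segmented independently on an in-process worker pool, and stitched by
   centroid ownership with IoU-based de-duplication.

Because no muscle imagery ships with the package, a synthetic generator
produces H&E-like images *with exact ground truth*, which is what all
training, tests and the acceptance script run on.

## The synthetic generator

`generate_image(synthetic_spec(...))` emulates the morphology that drives
the method, not the photometric detail of real slides:

* **Geometry**: seeded Voronoi tessellation with one Lloyd relaxation step
  — muscle fibers are convex and space-filling, and the relaxation evens
  out fiber sizes the way real fascicles look. The interstitial band is
  the set of pixels whose two nearest seeds are nearly equidistant
  (half-margin below `boundary_thickness`), plus a band along the image
  border.
* **Appearance**: per-cell eosin-like colour jitter
  (`cell_color_mean/std`), a band rendered towards white with strength
  `boundary_contrast`, Gaussian blur and additive pixel noise.
* **Degradation**: with probability `boundary_break_prob` the arc between
  one pair of adjacent cells is faded almost to the cell colour — the
  broken-boundary failure mode that motivates scoring whole regions
  instead of trusting every contour.

What it does *not* emulate: staining artefacts, out-of-focus regions,
non-convex or torn fibers, nuclei and capillaries. Passing tests on this
generator therefore demonstrate that the machinery (detector, candidate
generation, tree inference, tiling) works as specified, not that the
shipped defaults are tuned for any particular real dataset — on real
slides the SRF and the scorer must be retrained.

Default study conditions used throughout the tests and the acceptance
script: $512\times512$ images with 30 cells, `boundary_contrast = 0.5`,
no breaks, and two training images; the tiling check uses a
$1200\times1200$ image with 100 cells, tile size 600 and padding 300.
These sizes keep a full run on one CPU in the minutes range while leaving
every cell large enough (diameter $\approx$ 100–150 px) to be
non-trivial.

## The 13 feature channels

Per pixel: CIE-Lab colour (3), gradient magnitude of luminance at Gaussian
blur $\sigma = 0$ and $1.5$ (2), and oriented gradient energy
$|\cos\theta\,I_x + \sin\theta\,I_y|$ at $\theta \in \{0^\circ, 45^\circ,
90^\circ, 135^\circ\}$ at full and half resolution (8), for 13 channels.
Gradients are centred finite differences with replicated borders; the
half-scale channels use $2\times2$ block means and nearest-neighbour
upsampling. This orientation bank is the simplest one consistent with the
channel count and is invariant (as a sum) under $90^\circ$ rotations,
which the tests exercise.

All blurs in the package are direct separable convolutions rather than
FFT-based filters. This is a deliberate numerical choice: a direct
convolution at a pixel depends only on a finite neighbourhood, so the
contour map computed on a padded tile is *bit-identical* to the same area
of the full image. That property propagates through the whole pipeline
and is what makes the tiled and standalone results exactly equal
(`run_parallel()` vs `segment_cells()`), not merely close.

## Structured forest details

* **Label space.** Training targets come from `boundary_map()`: a pixel is
  a contour pixel iff it is interstitial (label 0) with a cell among its
  8 neighbours.
* **Class mapping.** Structured labels cannot be scored directly, so at
  *every node* the label patches are mapped to two classes: 256 sampled
  pixel pairs give a binary "same/different" vector per patch, the
  centred vectors are projected on their first principal direction (a few
  power iterations suffice), and the sign defines the class. Note that an
  all-zeros and an all-ones patch are equivalent under this mapping —
  a property the tests document.
* **Splits.** Candidate thresholds per feature are 16 *type-1* (observed
  value) quantiles, so every candidate realises an actual partition;
  splits maximise Gini information gain, ties broken towards the lowest
  feature index and threshold. Stopping: depth 32, fewer than 16 samples,
  purity, or no positive gain. Leaves store the member patch closest to
  the element-wise label mean.
* **Defaults.** 8 trees, per-tree row fraction 0.5 and feature fraction
  0.25, 64 candidate features per node, $d_\mathrm{in} = 32$,
  $d_\mathrm{out} = 16$, prediction stride 8. With binary leaf votes the
  accumulated sums are integers, so chunked parallel prediction is exactly
  associative — another ingredient of the tiling-equality contract.

## Watershed and the boundary representation

Flooding starts from the regional minima of the (smoothed,
$\sigma = 1$) contour map with a priority queue ordered by height and
raster position, growing basins 4-connectedly until every pixel belongs to
one. Boundaries are then drawn on the *crack* between regions: a pixel
becomes a boundary (0) pixel iff its down or right neighbour survives
with a different label, resolved in a single reverse raster scan. Two
consequences are provable and tested:

* no two distinct regions are ever 4-adjacent (closedness), and
* no $2\times2$ all-zero block exists (single-pixel width) — marking
  watershed *lines* on pixels instead provably violates this wherever
  four basins meet with diagonally approaching lines, which is why the
  crack representation was chosen.

Regions smaller than `min_region_area` (default 30 px, suppressing noise
minima from contour false positives) are merged into the neighbour with
the weakest shared boundary, smallest region first; merging relabels the
full raster and re-derives the boundaries, iterated to a fixed point.
Greedy strength-threshold merging (`threshold_merge()`) uses the same
engine with length-weighted recombination of $B$, and its outputs at
increasing thresholds are nested partitions.

All tie-breaks (queue order, merge order, id order) use raster-scan
region ids, so a tile crop reproduces the full image's decisions — once
more for the tiling contract.

## Scoring, cutting, inference

**Features (14).** area; perimeter (crack-edge count scaled by $\pi/4$, so
a digital disk scores its smooth perimeter); circularity $4\pi A/P^2$
clamped to $[0,1]$; solidity (convex hull of the boundary ring, Pick-style
area); eccentricity from central moments; mean and SD of each Lab channel;
mean contour strength on the boundary ring and in the interior; their
guarded ratio. For tree nodes these are aggregated exactly from per-leaf
sufficient statistics (regions never touch, so sums, crack counts, rings,
moments and hull points are additive), which makes scoring all $2N-1$
nodes linear in image size.

**Scorer.** A standard probability random forest
(`randomForest`, 200 trees) trained on *merge-tree nodes* of the training
images labelled positive iff their best IoU against a ground-truth cell
reaches 0.7 — so the scorer sees over-segmented fragments and correctly
merged cells alike.

**Cutting.** Adjacent regions whose (current, length-weighted) boundary
strength exceeds `cut_threshold` are never merged, so the tree decomposes
into independent subtrees and inference parallelises. The default 0.2
reflects vote dilution: an averaged structured-vote contour rarely exceeds
$\sim0.3$ even on a true boundary (only a fraction of the overlapping
leaf patches assert the exact line), so 0.2 separates inter-cell contours
from intra-cell false positives on the synthetic data. It is a config
value and should be recalibrated together with any retrained detector.

**Inference.** Subtrees with at most `max_exhaustive_leaves = 12` leaves
are solved exactly by enumerating all antichains (bounded by
$\sim 1.5\times10^4$ labelings at 12 leaves) with vectorised energies.
Larger subtrees use a two-stage surrogate: an exact unary-only dynamic
program on the tree (optimal when $\mu = 0$), then greedy local search
over flip / promote-to-parent / demote-to-children moves accepting only
strict energy decreases.

The trade-off constant defaults to $\mu = 0.005$. The pairwise magnitude
is $\mu\,e^{-B}L$ with boundary lengths $L$ of order $10^2$–$10^3$
pixels, while unary gains are of order 1; at $\mu \gtrsim 0.1$ the
pairwise term dominates every unary and inference degenerates to
selecting nothing in subtrees with long weak internal boundaries, so the
default scales the two terms to comparable magnitude. $\varepsilon =
10^{-6}$;
unselected nodes do contribute $-\log(1-s_i+\varepsilon)$, a convention
that matters when comparing absolute energies. Ties in exact inference
resolve to the lexicographically smallest selected set.

Cells whose node score falls below `score_threshold` (default 0.26, the
operating point used for reported precision/recall trade-offs) are
discarded; `pr_curve()` sweeps this threshold.

## Tiling

Cores form a disjoint grid (`tile_size`, default 1024); padded tiles add
`pad = 300` px per side, comfortably above any plausible fiber diameter.
Each padded tile runs the full pipeline with its contour-voting grid
aligned to global coordinates. A cell is kept by the unique tile whose
core contains its centroid; copies with mask IoU $> 0.5$ from different
tiles deduplicate toward the deeper centroid, and remaining partial overlaps
resolve to the earlier-kept cell. Because every stage is crop-consistent,
the stitched raster equals the standalone segmentation exactly (up to
renumbering) and is invariant to the worker count — both are asserted as
identities, not tolerances, in the tests.

## Evaluation conventions

Matching is greedy one-to-one by descending intersection area. Per-cell
$P = |S\cap G|/|S|$, $R = |S\cap G|/|G|$, $F_1$ harmonic. Image-level
averages penalise unmatched cells: unmatched segmented cells count
$P = 0$, unmatched ground-truth cells count $R = 0$, and the $F_1$
average divides by $\max(n_\mathrm{seg}, n_\mathrm{gt})$. The
matched-only alternative is available (`penalize_unmatched = FALSE`)
because the convention changes absolute numbers.

## Known limitations

* The generator's regularity makes the task easier than degraded clinical
  slides; reported synthetic metrics are an upper bound on realism.
* The scorer and the cut threshold are calibrated jointly with the
  detector; swapping any one component requires re-training/re-tuning.
* Local search on very large subtrees has no optimality guarantee beyond
  "never worse than the unary-only optimum"; the cut threshold is what
  keeps subtrees small in practice.
* Label rasters are written as 16-bit TIFF (8-bit PNG for ≤255 labels);
  no pyramid/whole-slide formats.
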