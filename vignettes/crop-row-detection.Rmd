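---
title: "Detecting crop rows: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting crop rows: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(croprows)
```

## The problem

A camera mounted on an agricultural vehicle looks down and forward over a
field of young row crops. For vision-based guidance the machine needs, per
frame, the image positions of the crop rows as straight lines. Two things
make this hard: perspective (parallel rows converge toward the horizon, so
"rows are parallel and evenly spaced" cannot be exploited directly in the
image), and weeds, which are green like the crop and can only be told apart
by geometry — crops sit on lines, weeds scatter between them.

`croprows` implements a detection chain built around those two
observations:

1. **Rectify.** A region of interest (ROI) is cropped and warped with a
   planar homography estimated from four point correspondences, so that in
   the rectified view crop rows run parallel and near-vertical.
2. **Segment.** Vegetation is separated from soil with the Excess Green
   index on chromaticity-normalized RGB, binarized by Otsu's method, and
   cleaned by morphological opening and closing.
3. **Cluster.** Foreground pixels are grouped by density-based clustering.
   Two geometric repair rules follow: if fewer clusters than expected rows
   are found, rows are assumed to be bridged by weeds and the
   lowest-density points are iteratively peeled off before re-clustering;
   if two clusters sit closer than one crop-row spacing, the smaller
   (then shorter) one is taken to be a weed patch and deleted.
4. **Fit.** One line per surviving cluster is fit with RANSAC, kept only if
   its slope lies in a window around vertical (default [70°, 110°]), and
   mapped back to the camera frame through the inverse homography.

Three classical baselines (filtered Hough transform, sliding-window least
squares, per-cluster least squares) consume the same masks and cluster
sets and emit the same line tables, so all methods are interchangeable in
the evaluation protocol.

## The geometry stage

A planar homography is a non-singular 3×3 matrix acting on homogeneous
image coordinates. With the scale fixed by $h_{33} = 1$ it has eight free
parameters; each point correspondence $(x, y) \mapsto (x', y')$ yields two
linear equations

$$x'(h_{31}x + h_{32}y + h_{33}) = h_{11}x + h_{12}y + h_{13}, \qquad
  y'(h_{31}x + h_{32}y + h_{33}) = h_{21}x + h_{22}y + h_{23},$$

so exactly four correspondences — no three collinear on either side —
determine the matrix through an 8×8 linear solve. `estimate_homography()`
solves the system directly and falls back to a least-squares solve if the
condition number exceeds 1e12; collinearity is declared when a triangle of
points has area below 1e-6 times the squared coordinate span (the
constraint is classical, the tolerance is ours). On noise-free
correspondences recovery is exact to below 1e-6 px, and the unit tests
hold it there.

Warping is by inverse mapping with bilinear interpolation. Two practical
details matter:

* The rectified rectangle generally does not coincide with the image of
  the ROI (a quadrilateral), so pixels near the rectified border can
  sample outside the ROI. They receive a fill value, and — crucially — a
  validity mask excludes them from segmentation: black fill has an Excess
  Green value of 0, which is *greener* than soil (≈ −0.2), and would
  otherwise masquerade as vegetation columns along the frame edges.
* The destination rectangle is chosen at the native scale of the
  rectified plane (the ROI quadrilateral's extent) rather than forced to
  the ROI's own width and height. Forcing the ROI size shrinks content by
  roughly the perspective foreshortening factor; with millimeter-scale
  crop blobs that pushes structures below the reach of the 3×3 opening
  kernel and visibly costs recall. Configs built by `scene_config()` set
  `rect_size` accordingly; it remains overridable.

## The segmentation stage

Channels are first scaled by their per-image maxima
($R_n = R/R_{max}$, …), then divided by the per-pixel sum
$r = R_n/(R_n+G_n+B_n)$ with a minute constant (1e-8) in the denominator
to guard against black pixels. Excess Green is $ExG = 2g - r - b$, which
under $r+g+b=1$ equals $3g-1$ and lies in $[-1, 2]$: 2 for pure green, 0
for gray, −1 for green-free pixels. Because the chromaticity transform
cancels any common scaling of the channels, multiplicative shadow bands
barely disturb it — the segmentation is illumination-robust by
construction, which is exactly why this index is standard in agronomic
imaging.

Otsu binarization operates on a fixed 256-bin rescaling of $[-1,2]$; the
threshold maximizes between-class variance by exhaustive scan, ties broken
toward the lowest threshold so the result is deterministic, and pixels
strictly above the threshold become vegetation. A constant field (a frame
with no contrast at all) yields an all-zero mask plus a warning flag
rather than an error. The suite checks the scan against an independent
brute-force oracle and cross-checks the threshold against
`EBImage::otsu()` to within one bin.

Cleanup is binary opening then closing with square 3×3 structuring
elements (both exposed in config; size 1 disables a stage). Opening
removes speckle smaller than the kernel, closing fills pinholes inside
blobs; both are idempotent, which the suite asserts.

## The clustering stage and its repair rules

No density-clustering package is available in this R stack, so the module
carries its own DBSCAN specialised to rasters: foreground pixels live on
the integer lattice, so neighbourhood counts come from shifting the mask
over an elliptical offset set, and cluster components from propagating
minimum labels across those offsets — no spatial index needed. Points
with at least `min_pts` neighbours (self included) are core; clusters are
maximal density-connected sets; everything else is an outlier. Clusters
smaller than `min_cluster_size` (default 50 px for the default ROI) are
dissolved into the outlier set; this is the detector's main tuning knob.

The neighbourhood is deliberately anisotropic, `eps = c(4, 20)` px in
(x, y). Rectified rows are vertical chains of blobs: along the row, gaps
of one or two missing plants (about 8–16 px at the default geometry) must
be bridged, while across rows the reach must stay well under the row
spacing (40 px) so adjacent rows never touch directly. An isotropic
radius cannot satisfy both. The elongated neighbourhood plays the role
that hierarchical density flexibility plays in HDBSCAN-based versions of
this pipeline.

Repair rule one (`ensure_min_rows()`): if fewer clusters than
`expected_rows` are found, the scene is assumed weed-bridged. Each
iteration removes the 10% of points with the lowest neighbourhood density
— bridges are sparser than rows — and re-clusters, up to 5 iterations.
Because peeling can also *fragment* a sparse scene rather than separate
it, the function returns the best iterate seen (most clusters), not the
last; peeled points are appended to the outliers so that clusters plus
outliers always partition the original foreground. Non-convergence is
reported in a flag, never raised.

Repair rule two (`prune_adjacent_clusters()`): clusters whose x-centroids
sit closer than `crop_row_distance_px` cannot both be rows. The cluster
ranked lower by size, with height breaking ties, is deleted (size first:
a weed patch may be tall but is rarely heavier than a crop row).
Deletions proceed in ascending rank order until no violating pair
remains. The distance threshold is a required configuration value;
synthetic-scene configs derive it as 0.6 × the generated row spacing.

## Robust line fitting

Lines are parameterized $x = a\,y + b$ — y as the regressor — so
near-vertical rows never produce infinite slopes. RANSAC samples two
distinct points, counts points within `residual_tol_px` perpendicular
distance, and keeps the consensus-maximal model; the iteration budget
adapts as $\lceil \log(1-c)/\log(1-w^2) \rceil$ with $c = 0.99$ and $w$
the best inlier ratio so far, capped at 500. The winning inlier set is
refit by least squares, then locally optimized: inliers are re-selected
against the refit line and refit again until the set stabilizes. Without
this step the consensus band can sit against one side of a row that is
wider than the tolerance, leaving a sub-pixel bias that plain least
squares does not have; with it, RANSAC matches least squares on clean
clusters (to 0.1°, asserted) and dominates it under contamination. The
pipeline's default tolerance is 3 px — about one row half-width at the
default geometry — while `ransac_line()` itself defaults to 2 px. A seed
parameter makes every fit reproducible without disturbing the caller's
RNG stream.

Endpoints are reported at the top and bottom edges of the rectified
frame, giving every method the same canonical extent, and back-projection
maps them through the inverse homography plus the ROI offset.

## Evaluation protocol

Each line becomes an axis-aligned box: the endpoint extent padded by
`half_width_px` in x (and in y only if the raw extent is degenerate).
Agreement is intersection-over-union of boxes; detections and truths are
matched greedily one-to-one by descending IOU, a match counting as a true
positive at IOU ≥ 0.5 by default. Precision is $tp/(tp+fp)$, recall
$tp/(tp+fn)$, and accuracy $tp/(tp+fp+fn)$ — the one standard definition
under which accuracy is dominated by both precision and recall, matching
how such counts are reported for this task. Ground-truth lines spanning
the full frame are clipped to the ROI's vertical span before scoring,
since detections only exist there. The box half-width for synthetic
scenes is 0.15 × the camera-frame row spacing.

## The synthetic field generator

`generate_field()` builds a top-view scene — vertical rows of green crop
blobs at regular spacing, each blob dropped with probability
`missing_crop_prob`; weed blobs (irregular unions of 2–5 disks, so that
opening removes only the smallest) Poisson-scattered over the inter-row
band; textured soil; optional multiplicative diagonal shadow bands — and
warps it to the camera frame with a projective tilt, emitting exact
ground-truth lines, vegetation and weed masks, and the four
correspondences that rectify the recommended ROI. Everything is
deterministic in the seed.

The default conditions are fixed once: a 480×360 camera frame whose top
edge is pinched to half width (a strongly tilted vehicle camera), a
central 120×80 ROI (about a quarter of the frame in each dimension),
three rows 40 px apart, crop blobs of radius 3 px every 8 px along the
row, soil speckle of 0.03. The *easy* preset has no weeds, no shadow and
5% missing plants; the *challenging* preset has 30% missing plants,
shadow bands at strength 0.5, and a weed density calibrated analytically
so weed area is roughly 30% of crop area (a weed blob covers ≈ 45 px² on
average). Weeds are restricted to the band between the outermost rows: in
a real field the margin beyond the scored rows holds the *next* crop
rows, not open weed banks, and scattering weeds there would manufacture
off-field structures no detector should be penalized (or rewarded) for.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: perspective-correct plant height (blobs are
flat ground-plane texture), color variation between crop species and weed
species (deliberate: the detector must not use color to split them),
occlusion and motion blur, curved rows, and ground-truth annotation bias.
Absolute IOU values on real imagery depend on annotation conventions;
only the relative ordering of methods and the direction of the ablation
are expected to transfer.

## Problem sizes and numerical choices

The statistical checks run 30 seeds per preset (90 scored rows), 100
seeded trials for the RANSAC robustness rate, and 40 seeds for the
Poisson law of weed counts — sizes at which every reported proportion has
a standard error small enough to separate the hypotheses being tested
while the whole suite stays comfortably interactive. Homography recovery
is asserted at 1e-6 px on exact input; warp round trips at 2 intensity
levels out of 255 on interior pixels; degenerate inputs (constant fields,
empty masks, singleton clusters, coincident points) return flagged empty
results or informative errors, never crashes, and frames with no
vegetation yield zero lines by contract.

## Known limitations

* Rows are modeled as straight lines; strongly curved rows would need a
  curve model the slope window would currently reject.
* The raster DBSCAN's label propagation is quadratic in cluster diameter
  over eps in the worst case; fine at ROI scale, not meant for full-frame
  clustering.
* The Hough baseline extracts edges as the morphological boundary of the
  binary mask (the exact edge set of a binary image) rather than running
  a Canny detector; on grayscale input a gradient-based edge detector
  would be required.
* Frames are processed independently — no temporal tracking; video input
  is handled as directories of numbered frames.
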