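---
title: "Methods: tassel branch segmentation and trait extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tassel branch segmentation and trait extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A maize tassel is a central spindle bearing 6–16 lateral branches whose
number, length, insertion angle and curvature are distinctness–uniformity–
stability (DUS) testing characters. Multi-view reconstruction delivers dense
colored point clouds of cut tassels, but the branches are thin, mutually
adherent near their bases, and tedious to segment by hand. `tasselseg`
implements an organ-level pipeline built around one key idea: only the
branch *tips* (the distal 3–5 cm, which are well separated in space) need to
be recognized by a learned model; everything below the tips is recovered
geometrically by shortest paths over the cloud.

The stages are:

1. **Preprocessing** — HSV color masking, statistical outlier removal,
   random then farthest-point downsampling (working resolution 4000 points),
   optional normal estimation.
2. **Tip segmentation** — a hierarchical point-set encoder–decoder
   (set-abstraction layers with multi-scale grouping; feature-propagation
   layers with inverse-distance-squared interpolation) labels each point
   branch-top (1) or remainder (0). In `"ground-truth-tips"` mode the
   pipeline instead trusts labels already on the cloud, which decouples the
   geometric stages from network quality.
3. **Instance clustering** — DBSCAN over the tip points with the adaptive
   radius eps = 3 × d_mean and minPts = 5.
4. **Skeletonization** — a shortest-path (Dijkstra) spanning tree over the
   downsampled remainder, rooted at the point maximizing the convex hull
   spanned with all branch growth points; per-branch paths; main-stem
   identification; fusion of every original point onto its nearest skeleton
   polyline.
5. **Traits** — branch count, per-branch length, insertion angle and
   curvature, tassel convex-hull volume, and dispersion (mean angle / 90°).

## Preprocessing choices

**Outlier filter.** The removal rule is the classical two-pass scheme: each
point's mean distance `mu_i` to its `n = 20` nearest neighbors, removal iff
`mu_i > mean(mu) + alpha * sd(mu)` with `alpha = 0.5`. Two readings were
rejected: removing individual neighbor *relations* is ill-defined for a
point set, and the subtracted form of the threshold (mean − alpha·sd) would
remove most of the cloud — with this filter family, larger `alpha` must keep
more points. Note that on perfectly clean data the rule still trims the
upper tail of the `mu` distribution (roughly a third under near-normal
spread); that is intrinsic to the method, harmless before farthest-point
resampling, and the reason the selectivity test measures *relative* removal
of injected outliers versus surface points.

**Downsampling.** The first-stage reduction is seeded uniform random
subsampling (the cited sampling-consensus step reduces to this when no model
is fitted, and re-seeding it is exactly the dataset-enhancement mechanism).
Farthest-point sampling (FPS) then equalizes density; it is pinned
deterministic by an explicit start index (default 1) with lowest-index
tie-breaks.

**Normals.** Smallest-eigenvalue eigenvector of the 16-NN covariance,
oriented away from the cloud centroid; any consistent orientation suffices
for the network, and centroid-outward is deterministic. Degenerate (rank <
2) neighborhoods fall back to +z with a warning.

## The tip-segmentation network

The encoder is three set-abstraction (SA) layers — FPS sampling, multi-scale
ball grouping, shared per-point MLP, max-pool per group — and the decoder is
three interpolate-and-PointNet (IP) layers — inverse-distance-squared 3-NN
interpolation, skip concatenation with the matching encoder scale, shared
MLP — followed by a shared fully connected head with dropout 0.5. Inputs are
coordinates plus unit normals (6 channels). The published account fixes this
topology but not the widths; the defaults (1024/256/global centroids) follow
the canonical multi-scale segmentation configuration and every width is
overridable. A reduced configuration (128/32/8 centroids) trains on one CPU
in minutes and is used by the trainability criterion.

The implementation is native R with C++ kernels for the geometric primitives
(FPS, ball query, grouped max-pool, k-NN). Because grouping depends only on
coordinates, the neighborhood structure is planned once per cloud and reused
across epochs; forward and backward passes are then dense matrix algebra.
Gradients are hand-derived and verified against finite differences in the
test suite. There is no batch normalization: at desk scale, He
initialization plus Adam is sufficient, and it keeps training exactly
reproducible for a fixed seed.

Training follows the published recipe: softmax cross-entropy (mean-reduced
rather than summed, so the learning rate is batch-size independent), Adam
with first-moment coefficient 0.9 and weight decay 1e-4, batch size 24,
initial learning rate 0.001 halved every 20 epochs, early stop when the
epoch loss falls below 0.001. The only augmentation is re-seeded random
subsampling, mirroring the stated enhancement scheme.

## Clustering

DBSCAN semantics are pinned exactly (ascending-index seed scan, FIFO
expansion, border points join the first core that reaches them) so the
brute-force oracle comparison is an identity, not a similarity. Clusters
below `min_cluster_size = 10` points are noise — the threshold is named but
not valued in the source; 10 rejects stray mislabeled boundary points at the
4000-point working resolution.

The adaptive radius is eps = 3 × d_mean computed *on the tip subset*. d_mean
is the mean distance over a 20-point neighborhood — the same neighborhood
statistic the outlier filter defines — rather than the single-nearest-
neighbor mean. After FPS, single-NN distances cluster near the covering
radius while the largest within-organ gaps approach twice it; a radius of
3 × single-NN mean is then too close to the worst gap and fragments tip
clusters into several instances per branch, whereas the 20-neighborhood
mean is a stable multiple of the sampling scale.

## Skeletonization

The bottom-up minimum-path construction is normalized to Dijkstra on the
radius graph (edges between points within radius r, weight = Euclidean
distance): the prose traversal is a best-first region growing that
approximates single-source shortest paths, and the Dijkstra reading realizes
"shortest path" exactly while removing traversal order as a correctness
hazard. The radius defaults to 3 × mean nearest-neighbor distance of the
nodes; unreachable subsets get their radius multiplied by 1.5 until the tree
spans all nodes (the "multi-layer" neighborhood), with a 20-round guard.

**Root selection** evaluates every node (growth points excluded) as the apex
of the convex hull formed with all growth points and takes the argmax — the
tassel base is the point most opposite the branch tops. With fewer than
three growth points every hull is degenerate (volume 0); the fallback is the
candidate maximizing the summed distance to the growth points, which keeps
single-branch inputs deterministic.

**Branch extent.** The skeleton is built over the remainder (non-tip)
points, so a growth point sits at the *base* of the labeled tip, about 4 cm
short of the branch's distal end. Because the trait of record is the path
length between the branch's two endpoints, each branch path is extended from
its growth point through its own tip instance to the farthest tip point by a
geodesic inside the instance. Without the extension, branch lengths are
short by the tip length — a 15–40% systematic error on 10–30 cm branches.

**Main-stem identification.** The source rule — the longest path is the
spindle — presumes the spindle's geodesic to the root is longer than any
branch's (attachment height + branch length). That holds for tassels whose
branches attach low, but in the stated synthetic world (branches on the
upper stem half, branch lengths to 30 cm, stems 25–40 cm) a lateral branch
usually out-measures the spindle, and misidentifying the stem corrupts every
downstream trait. The default rule is therefore *straightest-then-longest*:
a candidate path qualifies when its maximum turning angle (directions
averaged over ±2 cm of arc) stays below 15°, and the longest qualifier wins.
A lateral branch always turns by at least its insertion angle (≥ 20°) where
it leaves the stem, while the spindle runs nearly straight through the
branch zone, so the two are robustly separable; when no path qualifies, the
longest-path rule is the fallback, and `stem_rule = "longest"` restores the
original behavior.

**Fusion.** Every original point is assigned to the polyline (stem id −2,
then branches 0, 1, …) with minimal point-to-segment distance, ties to the
lower id with the stem first.

## Traits

- **Length**: polyline length from the distal tip node to the branch base
  (the first node shared with the main-stem path).
- **Angle**: between the secant from the base to the node at 25% of the
  branch's arc length, and the local stem direction (base toward the tassel
  top over 5 median node spacings of stem arc — a relative window, so the
  trait is scale-invariant; ~1.5 cm at the default resolution), in degrees. A near-base secant rather than
  the base→tip chord keeps drooping branches from inverting the angle; a
  *short* secant would be noise-dominated on jittered data. The 25% secant
  under-rotates relative to the true base tangent on curved branches; the
  generator's distally-concentrated curvature (below) keeps that bias small,
  and the fraction is a configurable parameter.
- **Curvature**: polyline length / endpoint chord, ≥ 1 by the triangle
  inequality.
- **Volume**: exact convex hull volume (incremental hull, farthest-first
  insertion, unit-normal plane tests with a 1e-9·scale tolerance; degenerate
  inputs return 0).
- **Dispersion**: mean insertion angle in radians / (π/2).
- **Count**: the number of non-stem tip instances. The generator labels the
  spindle top as an instance (it is morphologically a branch top, and
  without a spindle path there is no stem to measure angles against), so the
  usual case is n_instances − 1; a single-instance tassel reports 1 (that
  lone cluster *is* the count at the clustering stage) with empty per-branch
  lists and NA dispersion.

## The synthetic world

The generator emulates the statistical structure the pipeline assumes —
nothing more:

- **Stem**: near-vertical polyline, sinusoidal lateral wander of 0.05–0.25
  cm amplitude (≈ ≤ 4° of local tilt).
- **Branches**: quadratic Bézier curves. The control point lies along the
  drawn insertion-angle direction at 0.9 × chord, so the base tangent
  realizes the drawn angle *exactly*; the chord's droop angle is solved
  numerically so the arc/chord ratio equals the drawn curvature factor.
  Placing the control point far along the tangent concentrates bending
  distally — real branches emerge straight and arch toward the tip — and
  keeps the 25%-arc angle secant close to the base tangent.
- **Attachments**: sorted uniform heights on 0.50–0.85 of the stem (the
  spindle continues above the top attachment), golden-angle azimuths with
  ±15° jitter; more than 24 branches is rejected as infeasible.
- **Sampling**: stratified-uniform arc positions at `points_per_cm = 40`
  (dense and non-uniform, like reconstruction output; perfectly regular
  spacing would also make FPS tie-degenerate), isotropic Gaussian jitter of
  SD 0.15 cm standing in for surface thickness and reconstruction fuzz.
- **Labels**: the distal `tip_label_length = 4` cm of every branch and of
  the spindle, following the 3–5 cm annotation convention (enforced by the
  constructor).
- **Colors**: green-yellow HSV band that passes the default foreground mask;
  optional outliers are uniform in the 1.5× bounding box with a red hue the
  mask rejects.
- **Ground truth** is analytic: drawn angles are exact tangents, lengths and
  curvature ratios come from fine quadrature of the Bézier (2000-segment
  cumulative arc, error far below the 1e-6 documentation tolerance).

Defaults (6–16 branches, stems 25–40 cm, branch lengths 10–30 cm, angles
20–60°, curvature 1.0–1.4) follow the population statistics reported for
real material. "Noiseless" in the recovery tests means zero jitter and zero
outliers.

What a green test does *not* establish: the generator has no spikelets or
seed geometry, no missing-data holes at branch junctions, no crossing
branches (adherent or fully-fitted compact tassels are a stated failure mode
of the approach — crossing branches share points after fusion and bias
length, curvature and angle), and its color model is a band, not a
photorealistic rendering. Network scores on synthetic tassels say nothing
about scores on reconstructed field material.

## Numerical conventions

- All coordinates are centimetres; volumes cm³; angles degrees (dispersion
  converts to radians for the π/2 ratio).
- Tie-breaks are pinned everywhere: FPS and growth points to the lowest
  index, DBSCAN borders to the first-reaching core, equal-length main-stem
  candidates to the lowest instance, fusion ties to the stem then the lower
  branch id, prediction ties to class 0.
- Interpolation weights are 1/d²; a query coinciding with a support takes
  that support's feature exactly (no epsilon fudge).
- Cross-entropy clamps probabilities at 1e-12; probability rows sum to 1
  within 1e-5.
- PLY colors are uchar 0–255 (the de facto viewer dialect), so color
  round-trips are exact only for 8-bit-representable values; coordinates are
  stored as doubles in both PLY flavors.
- Acceptance-test sizes are desk-scale: structural criteria use tassels at
  reduced sampling density, and the Monte-Carlo volume oracle uses 4 × 10⁵
  samples on 5 of the 20 recovery tassels (standard error ≈ 0.1%, an order
  below the 1% tolerance), keeping the suite inside its runtime budget.

## Known limitations

- The straightest-path stem rule assumes the spindle wanders by less than
  the turn threshold per 2 cm window; a strongly kinked spindle would fall
  back to the longest-path rule.
- Heavily drooping branches (curvature factor well above ~1.5) are outside
  the generator's stated world and the angle convention degrades gracefully
  but measurably there.
- The PLY reader supports scalar vertex properties only (no list properties,
  no meshes), by design.
- Training is CPU-bound R; the full-size architecture is practical for
  inference and small studies, not for 1800-cloud training campaigns.
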