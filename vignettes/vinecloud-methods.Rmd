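---
title: "From colored point clouds to grapevine yield parameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From colored point clouds to grapevine yield parameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vinecloud)
```

## The problem

Vineyard yield is conventionally forecast from three parameters: the number
of grape bunches, the number of berries, and the berry diameter. Multi-view
stereo reconstruction of a camera rig driving along a row produces colored
3-D point clouds dense enough (about 1 mm point spacing after subsampling)
that individual berries are resolved as smooth "ridges" separated by
"valleys". `vinecloud` turns such a cloud, plus the bundle-adjusted camera
positions, into the three yield parameters. The pipeline has a fixed stage
order:

1. **Preprocessing** — brightness thresholding, statistical outlier removal,
   moving-least-squares smoothing, minimum-distance subsampling.
2. **Per-point features** — a 125-bin surface feature histogram (geometry)
   plus the three HSV color channels, 128 features per point.
3. **Classification** — an import vector machine yields per-point posterior
   probabilities for *grape bunch* vs. *canopy*.
4. **Label smoothing** — exact binary graph-cut minimization of a Potts
   energy built from the posteriors.
5. **Segmentation** — two-stage connected components with size filtering
   partitions bunch points into candidate bunches.
6. **findBerries** — randomized sphere fitting with a four-stage acceptance
   hierarchy detects berries per component.
7. **Yield report** — components with at least three berries constitute the
   bunch count; their berries are pooled for the berry count and diameter
   statistics.

All coordinates are stored in meters throughout; millimeter-scale field
parameters are converted once, at the configuration boundary
(`pipelineConfig()`).

## Preprocessing

Night-time acquisition against a black background produces dark phantom
points at object borders. Colors are converted by the exact hexcone
formulas (`rgbToHsv()`) and points with V below `vThreshold` (default 0.10)
are removed. The threshold is a scene property; it must sit above the
background brightness and below the darkest plant material.

The SOR filter computes each point's mean distance to its `sorK = 6`
nearest neighbors and removes points above the global mean plus
`sorSigmaMult = 1` standard deviation. MLS smoothing fits a weighted local
plane (Gaussian weights of scale `mlsRadius/2`, default radius 4 mm) and a
bivariate polynomial of order 2 over it, and projects each point onto the
fitted surface; points with fewer than `max(6, #coefficients)` neighbors
pass through unmoved rather than being dropped, so the stage never changes
the point count. 4 mm spans a berry flank without flattening the
valley-ridge relief. Exact planes and exactly quadratic height fields are
fixed points of this projection, which the test suite asserts to 1e-9 and
1e-6 respectively.

Subsampling is greedy over a spatial grid in storage order: a point
survives iff no earlier survivor lies within `subsampleMinDist` (default
1 mm — the density at which grapevine organ classification is known to
work and the reference density for every default further down). The
first-come rule makes the stage deterministic without an RNG.

## Surface feature histograms

For each point, all unordered pairs of valid-normal points within
`rH = 9 mm` (including the point itself) contribute one sample. For a pair
(source s, target t — the source is the point whose normal subtends the
smaller angle with the connecting vector), with u = n_s,
v = d̂ × u / |d̂ × u|, w = u × v, the three Darboux-frame features are

* f1 = v · n_t ∈ [−1, 1],
* f2 = u · d̂ ∈ [−1, 1],
* f3 = atan2(w · n_t, u · n_t) ∈ [−π, π].

Each feature is quantized into 5 equal-width bins over its analytic range
(upper edge closed), giving a joint 5 × 5 × 5 = 125-bin histogram,
normalized to sum 1 so the descriptor is robust to sampling density. The
construction uses only relative angles, so the histogram is invariant
under rigid motion — asserted to 1e-9 in the tests. Normals come from PCA
over `rN = 3 mm` neighborhoods and are oriented toward the nearest camera
position, which fixes the sign conventions; points with fewer than 3
neighbors get an undefined normal, points with fewer than 2 valid
neighbors get a zero histogram, and both are flagged invalid so the
classifier can fall back to the training prior.

The radii encode the organ geometry: berries have radius ≈ 6 mm, so 3 mm
captures a berry's slope and 9 mm spans about one and a half berries — the
valley-ridge signature — while leaves stay locally planar at that scale
and thick stems curve far less.

## Import vector machine

The classifier is sparse kernel logistic regression: an RBF kernel
expansion restricted to a greedily chosen subset of training points (the
import points), trained on ~600 points per class (balanced, as an analyst
would label). Features are standardized internally; the default bandwidth
is `gamma = 1/(p · median per-feature variance)` on standardized columns.
Each greedy step scores a seeded random subsample of ≤ 100 candidates by
the second-order (single-Newton-step) decrease of the regularized negative
log-likelihood that the candidate's kernel weight would achieve, adds the
best one, and refits all weights by damped Newton iterations. Selection
stops at a relative objective improvement below `tol = 1e-4` or at
`maxImport = 200` points. The output is a calibrated posterior; on a 1-D
two-Gaussian problem the posterior is asserted to track the closed-form
Bayes posterior within 0.1. Ties in the final argmax go to canopy, which
is conservative for bunch precision.

## Graph-cut label smoothing

Points are classified independently, so isolated errors appear inside
coherent regions. The smoothing energy is

E(L) = Σ_i (1 − P_i(L_i)) + penalty · #{(i,j) ∈ edges : L_i ≠ L_j},

with edges between all point pairs within `smoothRadius = 3 mm` (about
three subsampling distances) and `smoothPenalty = 0.5`. The bounded unary
cost 1 − P (rather than −log P) keeps any single point's influence
commensurate with one Potts edge. For two labels this energy is
submodular, so one s–t min-cut gives the exact global optimum; the
implementation reduces each node to a single terminal edge of capacity
|u0 − u1| (the constant Σ min(u0, u1) is added back) and solves max-flow
with igraph. Exactness is asserted against exhaustive enumeration on
≤ 15-node instances, and the achieved energy can never exceed the energy
of the argmax labeling.

## Segmentation

Bunch-labeled points are partitioned by single-linkage connected
components at `ccDist1 = 5 mm` (grid-bucketed union-find, identical to the
O(N²) oracle by construction). Components below `minPoints` (400 for
vertical-shoot-positioned rows, 300 for semi-minimal pruned hedge) are
deleted as residual classification noise; components above `maxPoints`
(5000 / 3000) usually fuse several bunches and are re-split at
`ccDist2 = 1 mm`, after which fragments are re-filtered with `minPoints` —
otherwise a split-off berry could later count as a bunch, inconsistent
with the three-berry rule.

## findBerries

The detector assumes its input is a grape bunch: spheres are the only
expected geometry. Repeatedly, a source point is drawn uniformly from the
remaining points (seeded); the initial sphere is fitted to the local patch
within `rMin` of the source — almost surely a single berry's surface —
falling back to the full `fitRadiusFactor · rMax` neighborhood when the
patch is too small or degenerate; the fit is an algebraic least-squares
sphere with one Gauss–Newton refinement, then iterated (≤ 3 times) on its
own inlier shell so the accepted sphere does not depend on which source
point seeded it. Fitting from the full neighborhood alone is unstable in
tight bunches because 1.2 · rMax spans adjacent berries.

Candidates pass a strict four-stage hierarchy (first failure reported):

1. **Radius**: within [`rMin`, `rMax`] = [4, 10] mm by default — the
   plausible berry range around the ~6 mm field radius.
2. **Support**: among points the 10%-inflated sphere encompasses, inliers
   are those within `inlierTol = 10%` of the radius from the surface; the
   inlier fraction must reach `minSupportRatio = 0.5` and the count
   `minFitPoints = 10`.
3. **Valley test**: a segment from the center toward the nearest camera
   (length r + `lineTol`) must contain at least `minLinePoints` cloud
   points within `lineTol = 1.5 mm`. A sphere on a berry has its crown
   there; a sphere wedged between berries has empty space — had a surface
   been on that line, the camera would have reconstructed it. The default
   `minLinePoints = 3` is calibrated against the 1 mm operating density:
   the tube's cap holds about 4–7 points over a true crown (area
   π · 1.5² ≈ 7 mm² at 0.7–1 points/mm²) and 0–1 over a valley, so 3
   tolerates Poisson thinning without admitting valleys.
4. **Overlap**: overlap ratio (r_a + r_b − ‖c_a − c_b‖)/(2 min(r_a, r_b))
   above `overlapRatio = 0.25` with an accepted berry triggers a support
   contest; the candidate wins only with strictly larger support, evicting
   the incumbent (whose support returns to the pool).

On acceptance the support points leave the remaining set (accepted support
sets are therefore pairwise disjoint) and the failure counter resets; the
loop stops after 2 × (current remaining count) consecutive failures — the
reset interpretation, so early luck cannot trigger a premature stop — or
when fewer than `minFitPoints` points remain. Termination is guaranteed
because acceptances strictly shrink the remaining set and failures are
bounded by the counter.

## Yield report and evaluation

Components with fewer than `minBerries = 3` berries are rejected; the
survivors constitute the bunch count, and their berries the berry count
and pooled diameter distribution. For evaluation, bunch components are
matched to reference bunches greedily by maximum point overlap, one to
one: a component fusing k true bunches yields one true positive and k − 1
false negatives; a bunch split into two components yields one true
positive and one false positive; unmatched components are false positives.
Berries are matched by an optimal one-to-one assignment (Hungarian
algorithm, validated against exhaustive enumeration) under a center
distance cap, and the RMSE of matched diameters accompanies
recall/precision.

## The synthetic scene generator

Field data for this problem require a camera rig and a commercial
reconstruction pipeline, so every stage is tested against generated scenes
with exact ground truth. The generator emulates the *reconstruction*, not
the imaging: berries (6 ± 0.5 mm radius) packed by sequential random
insertion inside an ellipsoidal envelope with center distances in
[r_i + r_j − overlap, r_i + r_j + packingGap] (the valley-ridge packing),
surfaces sampled at ~1 mm via Fibonacci lattices with interior points
removed; leaves as planar disks; stems as vertical cylinders at
trunk/cordon scale (12 mm radius — large enough that the 9 mm histogram
radius separates stem curvature from berry curvature, which is the regime
the radii were chosen for; thin shoots of berry-like curvature are a known
ambiguity of the descriptor and are not generated by default); one-sided
coverage emulated by keeping points whose outward normal faces at least
one camera on the track (0.6 m from the row, 15 cm steps, three heights),
leaves kept double-sided; Gaussian surface noise along the normal
(0.2 mm); sparse uniform outliers; and dark background points with
V < 0.08. Class colors are drawn from overlapping HSV models (bunch
≈ 90° ± 20°, S 0.40 ± 0.10, V 0.45 ± 0.10; canopy ≈ 110° ± 15°, S 0.60 ±
0.15, V 0.55 ± 0.15, both V-clamped at 0.12 so plant material never falls
under the background threshold) so that neither color nor geometry alone
is sufficient — the value of fusing both is itself a tested property.

`generateArtificialBunch()` is the analog of a caliper-verified reference
object: one bunch with diameters uniform in 15–20 mm, densely sampled
(0.5 mm) at very low noise (0.05 mm), optionally with the rear hemisphere
culled to emulate a one-sided field reconstruction.

What the generator deliberately does not reproduce: occlusion by
ray-casting (visibility is a normal-facing test), reconstruction artifacts
correlated across views, pedicels and thin shoots, natural berry
ellipticity, and within-bunch color gradients. Passing tests therefore
demonstrate correctness of the algorithms under the stated geometric
model, not field performance.

## Problem sizes and numerical choices

The test suite and acceptance checks run at desk scale, chosen so each
property is exercised well above its degeneracy threshold: the diameter
benchmark uses ~50 berries at 0.5 mm sampling (~160k points), the
repeatability benchmark 40 berries over 20 seeded runs, the end-to-end
recovery a 3 m row with 12 bunches (~90k points), and oracle equivalences
use exhaustive enumeration at ≤ 15 nodes (graph cut), ≤ 500 points
(connected components, SOR, subsampling) and ≤ 7 items (assignment).

Degenerate inputs are handled explicitly: coplanar sphere fits raise a
degenerate-fit error (the candidate is skipped), zero-radius or
out-of-range fits are rejected by stage 1, points without valid features
predict the training prior and are flagged, empty berry sets and empty
component lists produce all-zero reports, and recall/precision with a zero
denominator report 0 with a degeneracy flag. One RNG seed fans out to
per-stage seeds by stable hashing of the stage name, so any stage can be
re-run in isolation with identical results; all derived seeds stay below
2^31.

## Known limitations

* Only the camera-facing side of a row is reconstructed; like any
  one-sided survey, absolute counts underestimate the row total unless an
  empirical correction for the hidden side is applied downstream.
* The classifier is strictly binary (bunch vs. canopy); stems and leaves
  are not distinguished from each other.
* Components are processed independently; bunches touching within
  ~1–2 mm after the second split stage remain fused and count once.
* Berries are modeled as spheres; strongly elliptic berries bias the
  diameter estimate toward their mean curvature radius.
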