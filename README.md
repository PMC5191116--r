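# vinecloud

Yield parameter estimation from colored 3-D point clouds of grapevine
rows.

Vineyard yield is forecast from three parameters — the number of grape
bunches, the number of berries, and the berry diameter. Multi-view stereo
reconstruction of a camera rig driving along a row yields colored point
clouds dense enough (~1 mm point spacing after subsampling) to resolve
individual berries. `vinecloud` implements the full phenotyping pipeline
from such a cloud (plus the bundle-adjusted camera positions) to the yield
parameters:

1. **Preprocessing** — HSV brightness thresholding removes the dark
   night-time background; statistical outlier removal (mean k-nearest-
   neighbor distance above μ + ασ); moving-least-squares smoothing (local
   plane + order-2 polynomial projection); greedy 1 mm minimum-distance
   subsampling.
2. **Features** — per point, a pose-invariant 125-bin surface feature
   histogram over the r_H = 9 mm neighborhood (joint 5×5×5 histogram of
   the three Darboux-frame angles f1 = v·n_t, f2 = u·d̂,
   f3 = atan2(w·n_t, u·n_t), normals from r_N = 3 mm PCA oriented to the
   nearest camera) plus the three HSV channels: 128 features.
3. **Classification** — an import vector machine (sparse kernel logistic
   regression with greedily selected import points, ~600 training points
   per class) returns calibrated posteriors P(bunch | x).
4. **Label smoothing** — exact global minimization of
   E(L) = Σᵢ (1 − Pᵢ(Lᵢ)) + λ·#{(i,j) ∈ E : Lᵢ ≠ Lⱼ}
   over the 3 mm radius neighbor graph by a single s–t min-cut.
5. **Segmentation** — two-stage connected components (5 mm pass, size
   filter, 1 mm re-split of oversized components) yields candidate bunch
   components.
6. **findBerries** — randomized sphere fitting with a four-stage
   acceptance hierarchy (radius range, inlier support, valley test toward
   the nearest camera, overlap contest); stops after 2 × remaining
   consecutive failures.
7. **Report** — components with ≥ 3 berries form the bunch count; their
   berries give the berry count and diameter statistics. Scoring against
   reference data (point overlap matching for bunches, capped optimal
   assignment for berries) yields recall, precision and diameter RMSE.

A synthetic scene generator (`generateScene()`, `generateBunch()`,
`generateArtificialBunch()`) produces grapevine-like rows with exact
ground truth — berry packings with valley-ridge geometry, planar leaves,
stem cylinders, one-sided coverage, noise, outliers and dark background —
so that every stage is testable without field data.

## Worked example

Generate a synthetic row, train a classifier on a second row, and run the
pipeline end to end:

```r
library(vinecloud)

cfg <- pipelineConfig()                    # all defaults, VSP-style sizes

## a training row with ground-truth labels, and a model
train <- generateScene(sceneConfig(rowLength = 1, nBunches = 4,
                                   leafCount = 12, seed = 1))
model <- trainFromScene(train, cfg)$model

## a fresh 12-bunch row to measure
scene <- generateScene(sceneConfig(rowLength = 3, nBunches = 12,
                                   berriesPerBunch = c(8, 12),
                                   leafCount = 36, seed = 2))
res <- runPipeline(sceneCloud(scene), sceneCameras(scene), model, cfg)
res$report
```

```
YieldReport
  grape bunches: 12
  berries:       113
  berry diameter: 12.1 +/- 1.0 mm
```

The report says the pipeline counted 12 grape bunches, detected 113
berries in them, and estimated a mean berry diameter of 12.1 mm — against
a generator truth of 12 bunches and 6 ± 0.5 mm berry radii. With the
ground truth in hand the detections can be scored:

```r
scoreBunches(res$components, sceneTruth(scene)$bunchId[res$kept])
allBerries <- do.call(rbind, res$berries[res$report@retained])
scoreBerries(allBerries, sceneBerries(scene), matchDist = 0.006)
```

```
EvalResult: TP 12  FP 1  FN 0 | recall 1.000  precision 0.923
EvalResult: TP 113  FP 0  FN 3 | recall 0.974  precision 1.000  RMSE 0.000299 m
```

All 12 true bunches are recovered. Segmentation produced a 13th,
spurious component, which the three-berry rule then rejected from the
bunch count — it appears here as one bunch-level false positive because
`scoreBunches` scores all segmented components. 113 of 116 true berries
are found with no false detections, and the matched diameters agree with
the truth to an RMSE of 0.3 mm. Real field clouds carry occlusion and
reconstruction artifacts the generator does not emulate, so field recall
is expected to be lower (see the methods vignette).

Field data come in through `readPLY()` (ASCII or binary little-endian,
coordinates in meters, 8-bit or float colors) and `readCameraTrack()`
(3-column text). A thin command-line front end with `simulate`,
`preprocess`, `train` and `run` subcommands is installed at
`inst/scripts/vinecloud.R`.

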