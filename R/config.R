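#' Pipeline configuration
#'
#' Collects every tunable of the pipeline, with defaults appropriate for
#' MVS-reconstructed vineyard rows subsampled to ~1 mm point spacing. All
#' lengths are in meters (millimeter-scale field parameters are converted
#' here, at the configuration boundary).
#'
#' @param vThreshold HSV brightness threshold: points with V below it are
#'   removed as dark background (default 0.10).
#' @param sorK,sorSigmaMult statistical outlier removal: number of nearest
#'   neighbors and the sigma multiplier (defaults 6 and 1).
#' @param mlsRadius,mlsOrder moving-least-squares neighborhood radius
#'   (default 4 mm) and polynomial order (default 2).
#' @param subsampleMinDist minimum point-to-point distance after
#'   subsampling (default 1 mm).
#' @param rN,rH normal estimation radius (default 3 mm) and surface feature
#'   histogram radius (default 9 mm).
#' @param gamma RBF kernel bandwidth for the classifier; \code{NULL} picks
#'   1 / (p * median per-feature variance) on standardized features.
#' @param lambda,maxImport,tol classifier regularization, import point
#'   budget, and relative-improvement stopping tolerance.
#' @param smoothRadius,smoothPenalty label smoothing neighbor-graph radius
#'   (default 3 mm) and Potts penalty for diverging labels (default 0.5).
#' @param ccDist1,ccDist2 connected-component distance thresholds for the
#'   first pass (default 5 mm) and for splitting fused components
#'   (default 1 mm).
#' @param minPoints,maxPoints component size filter: smaller components are
#'   deleted, larger ones re-split (defaults 400 and 5000, the vertical
#'   shoot positioned trellis settings; use 300/3000 for semi-minimal
#'   pruned hedge rows).
#' @param rMin,rMax valid berry radius range (default 4-10 mm).
#' @param fitRadiusFactor sphere-fit neighborhood radius as a multiple of
#'   \code{rMax} (default 1.2).
#' @param inlierTol berry support tolerance: a point supports a sphere when
#'   its center distance is within this fraction of the radius (default 0.10).
#' @param minSupportRatio minimum inlier fraction among points the sphere
#'   encompasses (default 0.5).
#' @param minFitPoints minimum neighborhood size for a sphere fit (default 10).
#' @param lineTol,minLinePoints valley test: tube radius around the
#'   center-to-camera segment (default 1.5 mm) and the minimum number of
#'   cloud points inside it (default 3, calibrated to the ~1 mm point
#'   spacing of the subsampled cloud: a true berry crown offers about
#'   4-7 points in the tube, a valley 0-1).
#' @param overlapRatio maximum allowed overlap between accepted berries
#'   (default 0.25).
#' @param minBerries a component needs at least this many berries to count
#'   as a grape bunch (default 3).
#' @param seed base RNG seed fanned out to per-stage seeds.
#' @return A validated named list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(minPoints = 300, maxPoints = 3000)  # SMPH settings
#' cfg$ccDist1
#' @export
pipelineConfig <- function(vThreshold = 0.10,
                           sorK = 6L, sorSigmaMult = 1.0,
                           mlsRadius = 0.004, mlsOrder = 2L,
                           subsampleMinDist = 0.001,
                           rN = 0.003, rH = 0.009,
                           gamma = NULL, lambda = 1e-3,
                           maxImport = 200L, tol = 1e-4,
                           smoothRadius = 0.003, smoothPenalty = 0.5,
                           ccDist1 = 0.005, ccDist2 = 0.001,
                           minPoints = 400L, maxPoints = 5000L,
                           rMin = 0.004, rMax = 0.010,
                           fitRadiusFactor = 1.2,
                           inlierTol = 0.10, minSupportRatio = 0.5,
                           minFitPoints = 10L,
                           lineTol = 0.0015, minLinePoints = 3L,
                           overlapRatio = 0.25,
                           minBerries = 3L,
                           seed = 1L) {
  cfg <- list(
    vThreshold = vThreshold, sorK = as.integer(sorK),
    sorSigmaMult = sorSigmaMult, mlsRadius = mlsRadius,
    mlsOrder = as.integer(mlsOrder), subsampleMinDist = subsampleMinDist,
    rN = rN, rH = rH, gamma = gamma, lambda = lambda,
    maxImport = as.integer(maxImport), tol = tol,
    smoothRadius = smoothRadius, smoothPenalty = smoothPenalty,
    ccDist1 = ccDist1, ccDist2 = ccDist2,
    minPoints = as.integer(minPoints), maxPoints = as.integer(maxPoints),
    rMin = rMin, rMax = rMax, fitRadiusFactor = fitRadiusFactor,
    inlierTol = inlierTol, minSupportRatio = minSupportRatio,
    minFitPoints = as.integer(minFitPoints),
    lineTol = lineTol, minLinePoints = as.integer(minLinePoints),
    overlapRatio = overlapRatio, minBerries = as.integer(minBerries),
    seed = as.integer(seed)
  )
  lens <- c("mlsRadius", "subsampleMinDist", "rN", "rH", "smoothRadius",
            "ccDist1", "ccDist2", "rMin", "rMax", "lineTol")
  for (nm in lens) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) stop(nm, " must be > 0")
  }
  if (cfg$vThreshold < 0 || cfg$vThreshold > 1) stop("vThreshold must be in [0, 1]")
  if (cfg$sorK < 3) stop("sorK must be >= 3")
  if (cfg$sorSigmaMult <= 0) stop("sorSigmaMult must be > 0")
  if (!cfg$mlsOrder %in% 1:3) stop("mlsOrder must be 1, 2 or 3")
  if (cfg$rH <= cfg$rN) stop("rH must exceed rN")
  if (cfg$rMin >= cfg$rMax) stop("berry radius range requires rMin < rMax")
  if (cfg$ccDist2 >= cfg$ccDist1) stop("ccDist2 must be smaller than ccDist1")
  if (cfg$minPoints >= cfg$maxPoints) stop("minPoints must be below maxPoints")
  if (cfg$inlierTol <= 0 || cfg$inlierTol > 1) stop("inlierTol must be in (0, 1]")
  if (cfg$minSupportRatio <= 0 || cfg$minSupportRatio > 1) {
    stop("minSupportRatio must be in (0, 1]")
  }
  if (cfg$overlapRatio <= 0 || cfg$overlapRatio > 1) stop("overlapRatio must be in (0, 1]")
  if (cfg$smoothPenalty < 0) stop("smoothPenalty must be >= 0")
  class(cfg) <- "PipelineConfig"
  cfg
}

# Deterministic per-stage seed derived from the base seed and the stage name
# so each stage is independently reproducible. Kept below 2^31.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}
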