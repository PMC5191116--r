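#' Train a classifier from a synthetic scene
#'
#' Convenience wrapper for building a classification model from generated
#' ground truth: the scene is preprocessed, features are computed, a
#' balanced training set (default ~600 points per class, mirroring a
#' typical manual labeling effort) is drawn from the points with valid
#' features, and an import vector machine is trained. Points of the
#' background and outlier truth classes that survive preprocessing count
#' as canopy.
#'
#' @param scene a [SyntheticScene-class].
#' @param config a [pipelineConfig()].
#' @param perClass training points drawn per class (default 600).
#' @param featureSet "all" (default), "sfh" or "hsv": which feature block
#'   to train on.
#' @return list with \code{model} (an [IvmModel-class]) and
#'   \code{featureSet}.
#' @export
trainFromScene <- function(scene, config = pipelineConfig(), perClass = 600,
                           featureSet = c("all", "sfh", "hsv")) {
  featureSet <- match.arg(featureSet)
  stopifnot(is(scene, "SyntheticScene"))
  prep <- preprocessCloud(sceneCloud(scene), config)
  truthClass <- sceneTruth(scene)$class[prep$kept]
  y <- as.integer(truthClass == "bunch")

  cl <- estimateNormals(prep$cloud, config$rN, sceneCameras(scene))
  sfh <- computeSFH(cl, config$rH)
  feat <- computeFeatures(cl, sfh)
  feat <- .selectFeatures(feat, featureSet)
  valid <- attr(feat, "valid")

  set.seed(.stageSeed(config$seed, "train"))
  idx <- unlist(lapply(c(0L, 1L), function(k) {
    pool <- which(y == k & valid)
    sample(pool, min(perClass, length(pool)))
  }))
  model <- trainIVM(feat[idx, , drop = FALSE], y[idx],
                    gamma = config$gamma, lambda = config$lambda,
                    maxImport = config$maxImport, tol = config$tol,
                    seed = .stageSeed(config$seed, "ivm"))
  list(model = model, featureSet = featureSet)
}

.selectFeatures <- function(feat, featureSet) {
  v <- attr(feat, "valid")
  out <- switch(featureSet,
    all = feat,
    sfh = feat[, 1:125, drop = FALSE],
    hsv = feat[, 126:128, drop = FALSE]
  )
  attr(out, "valid") <- if (identical(featureSet, "hsv")) {
    rep(TRUE, nrow(out))
  } else {
    v
  }
  out
}

#' Run the full yield estimation pipeline
#'
#' Executes the fixed stage order on a raw cloud: preprocessing (background
#' removal, outlier removal, smoothing, subsampling), normal estimation,
#' surface feature histograms + HSV features, classification, graph-cut
#' label smoothing, two-stage connected-component segmentation, berry
#' detection per component, and yield finalization. Deterministic given
#' \code{config$seed} (each randomized stage gets a seed derived from the
#' base seed and the stage name).
#'
#' @param cloud the raw [PointCloud-class] (colors required), or a path to
#'   a PLY file.
#' @param cameras a [CameraTrack-class], or a path to a camera track file.
#' @param model a trained [IvmModel-class] (see [trainIVM()] /
#'   [trainFromScene()]); its feature layout must be the full 128-column
#'   set.
#' @param config a [pipelineConfig()].
#' @param featureSet feature block the model was trained on (default
#'   "all").
#' @return list with \code{report} (a [YieldReport-class]),
#'   \code{cloud} (the processed, labeled cloud), \code{components},
#'   \code{berries} (per component), \code{kept} (indices into the input
#'   cloud), and \code{manifest} (per-stage counts and the configuration).
#' @export
runPipeline <- function(cloud, cameras, model, config = pipelineConfig(),
                        featureSet = "all") {
  if (is.character(cloud)) cloud <- readPLY(cloud)
  if (is.character(cameras)) cameras <- readCameraTrack(cameras)
  if (missing(cameras) || is.null(cameras)) {
    stop("findBerries requires a camera track; none was supplied")
  }
  stopifnot(is(cloud, "PointCloud"), is(cameras, "CameraTrack"),
            is(model, "IvmModel"))

  prep <- preprocessCloud(cloud, config)
  cl <- estimateNormals(prep$cloud, config$rN, cameras)
  sfh <- computeSFH(cl, config$rH)
  feat <- .selectFeatures(computeFeatures(cl, sfh), featureSet)

  post <- predictIVM(model, feat)
  classPosteriors(cl) <- post
  graph <- buildNeighborGraph(cl, config$smoothRadius)
  sm <- smoothLabels(post, graph, config$smoothPenalty)
  pointLabels(cl) <- sm$labels

  seg <- segmentBunches(cl, config)
  xyz <- coords(cl)
  berries <- lapply(seq_along(seg$components), function(i) {
    findBerries(xyz[seg$components[[i]]$indices, , drop = FALSE], cameras,
                config, seed = .stageSeed(config$seed, paste0("berries", i)))
  })
  report <- finalizeYield(seg$components, berries, cloud = cl,
                          minBerries = config$minBerries)

  list(
    report = report, cloud = cl, components = seg$components,
    berries = berries, kept = prep$kept,
    manifest = list(
      counts = c(prep$counts,
                 bunchPoints = sum(sm$labels == 1L),
                 components = length(seg$components),
                 bunches = report@bunchCount,
                 berries = report@berryCount),
      energy = c(initial = sm$energyInitial, smoothed = sm$energy),
      config = unclass(config)
    )
  )
}
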