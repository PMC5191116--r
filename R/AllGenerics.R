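#' Accessors for PointCloud and friends
#'
#' @param x a [PointCloud-class], [CameraTrack-class] or
#'   [SyntheticScene-class] object.
#' @name accessors
NULL

#' @describeIn accessors number of points.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @describeIn accessors N x 3 coordinate matrix (meters).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @describeIn accessors N x 3 RGB matrix in \[0,1\] (NULL if absent).
#' @export
setGeneric("pointColors", function(x) standardGeneric("pointColors"))

#' @describeIn accessors N x 3 unit normal matrix (NULL if absent).
#' @export
setGeneric("pointNormals", function(x) standardGeneric("pointNormals"))

#' @describeIn accessors integer class labels (NULL if absent).
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' @describeIn accessors N x n class posterior matrix (NULL if absent).
#' @export
setGeneric("classPosteriors", function(x) standardGeneric("classPosteriors"))

#' @describeIn accessors M x 3 camera position matrix.
#' @export
setGeneric("cameraPositions", function(x) standardGeneric("cameraPositions"))

setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))
setMethod("coords", "PointCloud", function(x) x@coords)
setMethod("pointColors", "PointCloud", function(x)
  if (nrow(x@colors)) x@colors else NULL)
setMethod("pointNormals", "PointCloud", function(x)
  if (nrow(x@normals)) x@normals else NULL)
setMethod("pointLabels", "PointCloud", function(x)
  if (length(x@labels)) x@labels else NULL)
setMethod("classPosteriors", "PointCloud", function(x)
  if (nrow(x@posteriors)) x@posteriors else NULL)
setMethod("cameraPositions", "CameraTrack", function(x) x@positions)
setMethod("nPoints", "SyntheticScene", function(x) nPoints(x@cloud))

#' Replace labels / posteriors / normals of a PointCloud
#'
#' @param x a [PointCloud-class].
#' @param value replacement (NULL clears the slot).
#' @name setters
NULL

#' @rdname setters
#' @export
setGeneric("pointLabels<-", function(x, value) standardGeneric("pointLabels<-"))
#' @rdname setters
#' @export
setGeneric("classPosteriors<-", function(x, value) standardGeneric("classPosteriors<-"))
#' @rdname setters
#' @export
setGeneric("pointNormals<-", function(x, value) standardGeneric("pointNormals<-"))

setMethod("pointLabels<-", "PointCloud", function(x, value) {
  x@labels <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})
setMethod("classPosteriors<-", "PointCloud", function(x, value) {
  x@posteriors <- if (is.null(value)) matrix(numeric(0), 0, 2) else as.matrix(value)
  validObject(x)
  x
})
setMethod("pointNormals<-", "PointCloud", function(x, value) {
  x@normals <- if (is.null(value)) .emptyMat3() else as.matrix(value)
  validObject(x)
  x
})

#' Subset a PointCloud by point index
#'
#' All present per-point attributes (colors, normals, labels, posteriors)
#' are subset consistently; point order follows \code{i}.
#'
#' @param x a [PointCloud-class].
#' @param i integer or logical index vector.
#' @param j,...,drop ignored.
#' @return A [PointCloud-class].
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  new("PointCloud",
    coords = x@coords[i, , drop = FALSE],
    colors = if (nrow(x@colors)) x@colors[i, , drop = FALSE] else x@colors,
    normals = if (nrow(x@normals)) x@normals[i, , drop = FALSE] else x@normals,
    labels = if (length(x@labels)) x@labels[i] else x@labels,
    posteriors = if (nrow(x@posteriors)) x@posteriors[i, , drop = FALSE] else x@posteriors
  )
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud with %d points\n", nPoints(object)))
  has <- c(
    colors = nrow(object@colors) > 0, normals = nrow(object@normals) > 0,
    labels = length(object@labels) > 0, posteriors = nrow(object@posteriors) > 0
  )
  cat("  attributes:", if (any(has)) paste(names(has)[has], collapse = ", ") else "none", "\n")
  if (nPoints(object) > 0) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf(
      "  extent [m]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
      rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]
    ))
  }
})

setMethod("show", "CameraTrack", function(object) {
  cat(sprintf("CameraTrack with %d positions\n", nrow(object@positions)))
})

setMethod("show", "IvmModel", function(object) {
  cat(sprintf(
    "IvmModel: %d import points, gamma = %.4g, lambda = %.4g, prior(bunch) = %.3f\n",
    nrow(object@importPoints), object@gamma, object@lambda, object@prior
  ))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: TP %d  FP %d  FN %d | recall %.3f  precision %.3f%s%s\n",
    object@tp, object@fp, object@fn, object@recall, object@precision,
    if (is.na(object@rmse)) "" else sprintf("  RMSE %.4g m", object@rmse),
    if (object@degenerate) "  [degenerate]" else ""
  ))
})

setMethod("show", "YieldReport", function(object) {
  cat("YieldReport\n")
  cat(sprintf("  grape bunches: %d\n", object@bunchCount))
  cat(sprintf("  berries:       %d\n", object@berryCount))
  if (length(object@diameters)) {
    cat(sprintf(
      "  berry diameter: %.1f +/- %.1f mm\n",
      1000 * object@diameterMean, 1000 * object@diameterSd
    ))
  }
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d points, %d cameras, %d true berries in %d bunches\n",
    nPoints(object@cloud), nrow(cameraPositions(object@cameras)),
    nrow(object@berries),
    length(unique(object@berries$bunchId[!is.na(object@berries$bunchId)]))
  ))
})

#' @describeIn accessors the scene's point cloud.
#' @export
setGeneric("sceneCloud", function(x) standardGeneric("sceneCloud"))
#' @describeIn accessors the scene's camera track.
#' @export
setGeneric("sceneCameras", function(x) standardGeneric("sceneCameras"))
#' @describeIn accessors the scene's per-point ground truth data.frame.
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))
#' @describeIn accessors the scene's true berry table.
#' @export
setGeneric("sceneBerries", function(x) standardGeneric("sceneBerries"))

setMethod("sceneCloud", "SyntheticScene", function(x) x@cloud)
setMethod("sceneCameras", "SyntheticScene", function(x) x@cameras)
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)
setMethod("sceneBerries", "SyntheticScene", function(x) x@berries)
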