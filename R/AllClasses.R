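#' @useDynLib vinecloud, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.emptyMat3 <- function() matrix(numeric(0), nrow = 0, ncol = 3)

#' PointCloud: a colored 3-D point cloud
#'
#' The central container of the package. Coordinates are stored in meters.
#' Colors are RGB in \[0, 1\] (8-bit sources are divided by 255 on load).
#' Normals, per-point class labels and class posterior probabilities are
#' optional and empty until the corresponding pipeline stage fills them in.
#' Rows of the optional slots always align with \code{coords}; an optional
#' slot is either absent (zero rows / zero length) or complete.
#'
#' @slot coords N x 3 numeric matrix, finite, meters.
#' @slot colors N x 3 numeric matrix in \[0, 1\], or 0-row matrix if absent.
#' @slot normals N x 3 numeric matrix of unit vectors (rows of \code{NA} mark
#'   points whose normal is undefined), or 0-row matrix if absent.
#' @slot labels integer vector of length N with values in \{0, ..., n-1\}
#'   (0 = canopy, 1 = grape bunch in the binary pipeline), or length 0.
#' @slot posteriors N x n numeric matrix; each row is a probability vector
#'   summing to 1, or 0-row matrix if absent.
#'
#' @seealso [pointCloud()], [readPLY()], [coords()]
#' @exportClass PointCloud
setClass("PointCloud",
  representation(
    coords = "matrix",
    colors = "matrix",
    normals = "matrix",
    labels = "integer",
    posteriors = "matrix"
  ),
  prototype(
    coords = matrix(numeric(0), 0, 3),
    colors = matrix(numeric(0), 0, 3),
    normals = matrix(numeric(0), 0, 3),
    labels = integer(0),
    posteriors = matrix(numeric(0), 0, 2)
  )
)

setValidity("PointCloud", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3) return("coords must have 3 columns")
  if (n > 0 && !all(is.finite(object@coords))) return("coords must be finite")
  if (nrow(object@colors) > 0) {
    if (nrow(object@colors) != n || ncol(object@colors) != 3)
      return("colors must be N x 3")
    if (any(object@colors < -1e-12 | object@colors > 1 + 1e-12))
      return("colors must lie in [0, 1]")
  }
  if (nrow(object@normals) > 0) {
    if (nrow(object@normals) != n || ncol(object@normals) != 3)
      return("normals must be N x 3")
    nrm <- sqrt(rowSums(object@normals^2))
    ok <- is.na(nrm) | abs(nrm - 1) <= 1e-9
    if (!all(ok)) return("normals must be unit vectors (or NA rows)")
  }
  if (length(object@labels) > 0 && length(object@labels) != n)
    return("labels must have length N")
  if (nrow(object@posteriors) > 0) {
    if (nrow(object@posteriors) != n) return("posteriors must have N rows")
    if (any(object@posteriors < -1e-12 | object@posteriors > 1 + 1e-12))
      return("posteriors must lie in [0, 1]")
    if (any(abs(rowSums(object@posteriors) - 1) > 1e-9))
      return("posterior rows must sum to 1")
  }
  TRUE
})

#' Construct a PointCloud
#'
#' @param coords N x 3 numeric matrix of coordinates in meters.
#' @param colors optional N x 3 RGB matrix in \[0, 1\].
#' @param normals optional N x 3 matrix of unit normals (NA rows allowed).
#' @param labels optional integer vector of per-point class labels.
#' @param posteriors optional N x n matrix of class posteriors.
#' @return A [PointCloud-class] object.
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), 10, 3))
#' nPoints(pc)
#' @export
pointCloud <- function(coords, colors = NULL, normals = NULL, labels = NULL,
                       posteriors = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("PointCloud",
    coords = coords,
    colors = if (is.null(colors)) .emptyMat3() else {
      m <- as.matrix(colors); storage.mode(m) <- "double"; m
    },
    normals = if (is.null(normals)) .emptyMat3() else {
      m <- as.matrix(normals); storage.mode(m) <- "double"; m
    },
    labels = if (is.null(labels)) integer(0) else as.integer(labels),
    posteriors = if (is.null(posteriors)) matrix(numeric(0), 0, 2) else {
      m <- as.matrix(posteriors); storage.mode(m) <- "double"; m
    }
  )
}

#' CameraTrack: ordered camera positions along the acquisition path
#'
#' Camera positions (from the bundle-adjusted reconstruction, or synthetic)
#' in the same coordinate frame as the point cloud. Used to orient normals
#' and by the valley test of [findBerries()].
#'
#' @slot positions M x 3 numeric matrix, finite, meters, in travel order.
#' @seealso [cameraTrack()], [readCameraTrack()]
#' @exportClass CameraTrack
setClass("CameraTrack", representation(positions = "matrix"))

setValidity("CameraTrack", function(object) {
  if (ncol(object@positions) != 3) return("positions must have 3 columns")
  if (nrow(object@positions) < 1) return("need at least one camera position")
  if (!all(is.finite(object@positions))) return("positions must be finite")
  TRUE
})

#' Construct a CameraTrack
#' @param positions M x 3 numeric matrix of camera positions (meters).
#' @return A [CameraTrack-class] object.
#' @export
cameraTrack <- function(positions) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  new("CameraTrack", positions = positions)
}

#' IvmModel: sparse kernel logistic regression classifier
#'
#' Fitted import vector machine: a kernel logistic regression model whose
#' kernel expansion is restricted to a greedily selected subset of the
#' training points (the import points). Predictions are calibrated class
#' posterior probabilities.
#'
#' @slot importPoints S x p matrix of import points in standardized feature
#'   space.
#' @slot alpha numeric vector of length S, kernel expansion weights.
#' @slot bias numeric scalar intercept.
#' @slot gamma RBF kernel bandwidth (on standardized features).
#' @slot lambda ridge regularization weight.
#' @slot center,scale per-column standardization parameters (length p).
#' @slot prior training prior probability of class 1 (grape bunch).
#' @slot nll final regularized negative log-likelihood (training objective).
#' @seealso [trainIVM()], [predictIVM()]
#' @exportClass IvmModel
setClass("IvmModel",
  representation(
    importPoints = "matrix", alpha = "numeric", bias = "numeric",
    gamma = "numeric", lambda = "numeric",
    center = "numeric", scale = "numeric",
    prior = "numeric", nll = "numeric"
  )
)

setValidity("IvmModel", function(object) {
  if (nrow(object@importPoints) < 1) return("need at least one import point")
  if (length(object@alpha) != nrow(object@importPoints))
    return("alpha length must equal number of import points")
  if (object@gamma <= 0 || object@lambda <= 0)
    return("gamma and lambda must be positive")
  TRUE
})

#' EvalResult: detection scores against reference data
#'
#' Holds true/false positive and false negative counts with the derived
#' recall and precision, and (for berries) the RMSE of matched diameters.
#' Recall and precision are defined as 0 (with \code{degenerate = TRUE})
#' when their denominator is 0.
#'
#' @slot tp,fp,fn integer counts.
#' @slot recall,precision fractions in \[0, 1\].
#' @slot rmse root-mean-square error of matched diameters (meters; NA when
#'   no diameters were compared).
#' @slot degenerate TRUE when a denominator was 0.
#' @seealso [scoreBunches()], [scoreBerries()]
#' @exportClass EvalResult
setClass("EvalResult",
  representation(
    tp = "integer", fp = "integer", fn = "integer",
    recall = "numeric", precision = "numeric", rmse = "numeric",
    degenerate = "logical"
  )
)

.evalResult <- function(tp, fp, fn, rmse = NA_real_) {
  deg <- (tp + fn) == 0 || (tp + fp) == 0
  new("EvalResult",
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    rmse = rmse, degenerate = deg
  )
}

#' YieldReport: final yield parameters of a processed row
#'
#' @slot bunchCount number of components retained as grape bunches (those
#'   with at least \code{minBerries} detected berries).
#' @slot berryCount total number of berries over retained components.
#' @slot diameters pooled berry diameters (meters) of retained components.
#' @slot diameterMean,diameterSd summary of \code{diameters} (meters).
#' @slot componentBerries list of per-component berry tables (all candidate
#'   components, including rejected ones).
#' @slot retained logical vector marking which components were retained.
#' @slot perMeter data.frame of bunch/berry counts per 1 m bin along the
#'   row axis (first principal axis), or 0-row data.frame.
#' @seealso [finalizeYield()]
#' @exportClass YieldReport
setClass("YieldReport",
  representation(
    bunchCount = "integer", berryCount = "integer",
    diameters = "numeric", diameterMean = "numeric", diameterSd = "numeric",
    componentBerries = "list", retained = "logical",
    perMeter = "data.frame"
  )
)

#' SyntheticScene: generated grapevine scene with ground truth
#'
#' @slot cloud the generated [PointCloud-class] (colors always present).
#' @slot cameras the synthetic [CameraTrack-class].
#' @slot truth data.frame with one row per point: \code{class} (one of
#'   "bunch", "canopy", "background", "outlier"), \code{bunchId},
#'   \code{berryId} (NA outside bunches).
#' @slot berries data.frame of true berries: center \code{x,y,z}, radius
#'   \code{r} (meters), \code{bunchId}.
#' @slot config the generating configuration list.
#' @seealso [generateScene()], [generateBunch()], [generateArtificialBunch()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    cloud = "PointCloud", cameras = "CameraTrack",
    truth = "data.frame", berries = "data.frame", config = "list"
  )
)

setValidity("SyntheticScene", function(object) {
  if (nrow(object@truth) != nPoints(object@cloud))
    return("truth must have one row per point")
  TRUE
})
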