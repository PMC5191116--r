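#' Estimate oriented point normals
#'
#' The normal of each point is the smallest-eigenvalue eigenvector of the
#' covariance of its neighbors within \code{rN}, flipped so it points
#' toward the nearest camera position (the viewing side of a one-sided MVS
#' reconstruction). Points with fewer than 3 neighbors (including
#' themselves) get an undefined normal (\code{NA} row) and are excluded
#' from the surface feature histograms.
#'
#' @param cloud a nonempty [PointCloud-class].
#' @param rN neighborhood radius in meters (default 3 mm).
#' @param cameras a [CameraTrack-class].
#' @return The cloud with its \code{normals} slot filled.
#' @export
estimateNormals <- function(cloud, rN = 0.003, cameras) {
  stopifnot(is(cloud, "PointCloud"), is(cameras, "CameraTrack"))
  if (!is.numeric(rN) || rN <= 0) stop("rN must be > 0")
  if (nPoints(cloud) == 0) stop("empty cloud")
  res <- .cppEstimateNormals(coords(cloud), rN, cameraPositions(cameras))
  normals <- res$normals
  normals[!res$valid, ] <- NA_real_
  pointNormals(cloud) <- normals
  cloud
}

#' Surface feature histograms (SFH)
#'
#' The pose-invariant geometric descriptor of the pipeline: for each point,
#' all unordered pairs of valid-normal points within \code{rH} of it
#' (including the point itself) contribute three Darboux-frame angle
#' features computed from the two positions and normals, with the source
#' point of each pair chosen as the one whose normal subtends the smaller
#' angle with the connecting vector. Each feature is quantized into 5
#' equal-width bins over its analytic range (\[-1,1\], \[-1,1\],
#' \[-pi,pi\]; top edge closed) and the joint 5 x 5 x 5 = 125-bin histogram
#' is normalized to sum 1. Points with fewer than 2 neighbors get a zero
#' histogram and are flagged invalid.
#'
#' @param cloud a [PointCloud-class] with normals (see [estimateNormals()]).
#' @param rH histogram neighborhood radius in meters (default 9 mm,
#'   spanning about one and a half berries).
#' @return N x 125 matrix of bin frequencies with a logical attribute
#'   \code{"valid"}.
#' @export
computeSFH <- function(cloud, rH = 0.009) {
  stopifnot(is(cloud, "PointCloud"))
  normals <- pointNormals(cloud)
  if (is.null(normals)) stop("computeSFH requires normals; run estimateNormals first")
  valid <- !is.na(normals[, 1])
  normals0 <- normals
  normals0[!valid, ] <- 0
  res <- .cppComputeSfh(coords(cloud), normals0, valid, rH)
  sfh <- res$sfh
  attr(sfh, "valid") <- as.logical(res$valid)
  sfh
}

#' Assemble the 128-dimensional per-point feature matrix
#'
#' Concatenates the 125 SFH bin frequencies with the three HSV color
#' features (hue scaled from degrees to \[0, 1\]).
#'
#' @param cloud a [PointCloud-class] with colors.
#' @param sfh the N x 125 matrix from [computeSFH()].
#' @return N x 128 matrix (columns \code{sfh1..sfh125, h, s, v}) with the
#'   logical \code{"valid"} attribute propagated from the SFH block.
#' @export
computeFeatures <- function(cloud, sfh) {
  stopifnot(is(cloud, "PointCloud"))
  if (is.null(pointColors(cloud))) stop("computeFeatures requires colors")
  sfhM <- unclass(sfh)
  if (nrow(sfhM) != nPoints(cloud) || ncol(sfhM) != 125) {
    stop("sfh must be N x 125 and match the cloud")
  }
  hsv <- rgbToHsv(pointColors(cloud))
  out <- cbind(sfhM, hsv[, "h"] / 360, hsv[, "s"], hsv[, "v"])
  colnames(out) <- c(paste0("sfh", 1:125), "h", "s", "v")
  valid <- attr(sfh, "valid")
  attr(out, "valid") <- if (is.null(valid)) rep(TRUE, nrow(out)) else valid
  out
}
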