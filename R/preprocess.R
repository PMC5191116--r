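#' RGB to HSV conversion (hexcone model)
#'
#' Converts RGB values in \[0, 1\] to hue (degrees in \[0, 360)),
#' saturation and value in \[0, 1\]. Achromatic colors get hue 0 by
#' convention.
#'
#' @param colors N x 3 RGB matrix with values in \[0, 1\].
#' @return N x 3 matrix with columns \code{h}, \code{s}, \code{v}.
#' @examples
#' rgbToHsv(matrix(c(1, 0, 0), 1))   # pure red: 0, 1, 1
#' @export
rgbToHsv <- function(colors) {
  colors <- as.matrix(colors)
  if (ncol(colors) != 3) stop("colors must be N x 3")
  if (nrow(colors) > 0 &&
      (any(!is.finite(colors)) || any(colors < 0) || any(colors > 1))) {
    stop("RGB values must lie in [0, 1]")
  }
  r <- colors[, 1]; g <- colors[, 2]; b <- colors[, 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  chrom <- d > 0
  i <- chrom & mx == r
  h[i] <- 60 * (((g[i] - b[i]) / d[i]) %% 6)
  i <- chrom & mx == g & mx != r
  h[i] <- 60 * ((b[i] - r[i]) / d[i] + 2)
  i <- chrom & mx == b & mx != r & mx != g
  h[i] <- 60 * ((r[i] - g[i]) / d[i] + 4)
  h <- h %% 360
  s <- ifelse(mx > 0, d / mx, 0)
  cbind(h = h, s = s, v = mx)
}

#' HSV to RGB conversion
#'
#' Inverse of [rgbToHsv()]; used by the synthetic scene generator's color
#' models.
#'
#' @param hsv N x 3 matrix: hue in degrees, saturation and value in \[0, 1\].
#' @return N x 3 RGB matrix in \[0, 1\].
#' @export
hsvToRgb <- function(hsv) {
  hsv <- as.matrix(hsv)
  h <- (hsv[, 1] %% 360) / 60
  s <- pmin(pmax(hsv[, 2], 0), 1)
  v <- pmin(pmax(hsv[, 3], 0), 1)
  c <- v * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- v - c
  k <- floor(h) %% 6
  r <- ifelse(k == 0 | k == 5, c, ifelse(k == 1 | k == 4, x, 0))
  g <- ifelse(k == 1 | k == 2, c, ifelse(k == 0 | k == 3, x, 0))
  b <- ifelse(k == 3 | k == 4, c, ifelse(k == 2 | k == 5, x, 0))
  cbind(r + m, g + m, b + m)
}

#' Remove dark background points by brightness thresholding
#'
#' MVS reconstructions of night-time acquisitions contain dark phantom
#' points from the black background and mixed border pixels. The cloud's
#' colors are converted to HSV and every point whose V (brightness) falls
#' below the threshold is removed.
#'
#' @param cloud a [PointCloud-class] with colors.
#' @param vThreshold brightness threshold in \[0, 1\]; points with
#'   \code{V < vThreshold} are removed.
#' @return list with \code{cloud} (the retained points) and \code{removed}
#'   (integer indices into the input).
#' @export
removeBackground <- function(cloud, vThreshold = 0.10) {
  stopifnot(is(cloud, "PointCloud"))
  if (is.null(pointColors(cloud))) stop("background removal needs colors")
  v <- rgbToHsv(pointColors(cloud))[, "v"]
  removed <- which(v < vThreshold)
  keep <- if (length(removed)) cloud[-removed] else cloud
  list(cloud = keep, removed = removed)
}

#' Statistical outlier removal (SOR)
#'
#' For every point the mean distance to its \code{k} nearest neighbors is
#' computed; points whose mean distance exceeds the global mean plus
#' \code{sigmaMult} standard deviations of these distances are removed.
#'
#' @param cloud a [PointCloud-class] with more than \code{k} points.
#' @param k number of nearest neighbors (>= 3).
#' @param sigmaMult standard-deviation multiplier; larger keeps more points
#'   (\code{Inf} keeps all).
#' @return list with \code{cloud}, \code{removed} (indices into the input)
#'   and \code{meanDist} (the per-point mean kNN distances).
#' @export
sorFilter <- function(cloud, k = 6, sigmaMult = 1.0) {
  stopifnot(is(cloud, "PointCloud"))
  k <- as.integer(k)
  if (k < 1) stop("k must be positive")
  if (nPoints(cloud) <= k) stop("SOR needs more points than k")
  d <- .cppMeanKnnDist(coords(cloud), k)
  thr <- mean(d) + sigmaMult * stats::sd(d)
  removed <- which(d > thr)
  keep <- if (length(removed)) cloud[-removed] else cloud
  list(cloud = keep, removed = removed, meanDist = d)
}

#' Moving-least-squares surface smoothing
#'
#' Each point is projected onto a local polynomial surface: a weighted
#' plane is fitted to the neighbors within \code{radius} (Gaussian weights
#' of scale \code{radius/2}), a bivariate polynomial of the given order is
#' fitted to the neighbor heights over that plane, and the point is moved
#' onto the polynomial. Points with fewer than \code{max(6, #coefficients)}
#' neighbors pass through unmoved. Point count, order and all attributes
#' are preserved.
#'
#' @param cloud a [PointCloud-class].
#' @param radius neighborhood radius in meters (> 0).
#' @param order polynomial order: 1, 2 or 3.
#' @return The smoothed [PointCloud-class].
#' @export
mlsSmooth <- function(cloud, radius = 0.004, order = 2) {
  stopifnot(is(cloud, "PointCloud"))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  order <- as.integer(order)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  if (nPoints(cloud) == 0) return(cloud)
  newCoords <- .cppMlsSmooth(coords(cloud), radius, order)
  initialize(cloud, coords = newCoords)
}

#' Minimum-distance subsampling
#'
#' Greedy thinning over a spatial grid: points are visited in storage order
#' and kept iff no previously kept point lies within \code{dMin}. The
#' result is a subset of the input whose pairwise distances are all
#' >= \code{dMin}; ties are broken deterministically in favor of the
#' earlier point.
#'
#' @param cloud a [PointCloud-class].
#' @param dMin minimum point-to-point distance in meters (default 1 mm).
#' @return list with \code{cloud} and \code{kept} (indices into the input).
#' @export
subsampleMinDist <- function(cloud, dMin = 0.001) {
  stopifnot(is(cloud, "PointCloud"))
  if (!is.numeric(dMin) || dMin <= 0) stop("dMin must be > 0")
  if (nPoints(cloud) == 0) return(list(cloud = cloud, kept = integer(0)))
  keep <- .cppSubsampleMinDist(coords(cloud), dMin)
  list(cloud = cloud[keep], kept = which(keep))
}

#' Full preprocessing chain
#'
#' Runs the fixed cleanup order on a raw cloud: background removal ->
#' statistical outlier removal -> MLS smoothing -> minimum-distance
#' subsampling.
#'
#' @param cloud the raw [PointCloud-class] (colors required).
#' @param config a [pipelineConfig()].
#' @return list with \code{cloud} (the cleaned cloud), \code{kept}
#'   (indices of surviving points in the input cloud) and \code{counts}
#'   (points remaining after each stage).
#' @export
preprocessCloud <- function(cloud, config = pipelineConfig()) {
  stopifnot(is(cloud, "PointCloud"))
  n0 <- nPoints(cloud)
  kept <- seq_len(n0)

  bg <- removeBackground(cloud, config$vThreshold)
  if (length(bg$removed)) kept <- kept[-bg$removed]
  cl <- bg$cloud

  sor <- sorFilter(cl, config$sorK, config$sorSigmaMult)
  if (length(sor$removed)) kept <- kept[-sor$removed]
  cl <- sor$cloud

  cl <- mlsSmooth(cl, config$mlsRadius, config$mlsOrder)

  sub <- subsampleMinDist(cl, config$subsampleMinDist)
  kept <- kept[sub$kept]
  cl <- sub$cloud

  list(
    cloud = cl, kept = kept,
    counts = c(
      input = n0,
      background = n0 - length(bg$removed),
      sor = nPoints(sor$cloud),
      mls = nPoints(sor$cloud),
      subsample = nPoints(cl)
    )
  )
}
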