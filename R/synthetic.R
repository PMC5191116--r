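## Synthetic grapevine scenes with full ground truth. The generator
## emulates what a multi-view-stereo reconstruction of a trellis-trained
## row looks like after subsampling: ~1 mm point spacing, berries of
## ~6 mm radius forming valley-ridge geometry, locally planar leaves,
## cylindrical stems, one-sided coverage (points facing the camera track),
## surface noise, sparse outliers, and dark background points.

# deterministic, evenly spread unit-sphere directions (Fibonacci lattice)
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

.randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform over rotations
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# sample a sphere surface at approximately `spacing` point-to-point distance
.sampleSphere <- function(center, r, spacing) {
  n <- max(4L, round(4 * pi * r^2 / spacing^2 / 1.10))
  dirs <- .fibonacciSphere(n) %*% .randomRotation()
  list(points = sweep(dirs * r, 2, center, `+`), normals = dirs)
}

# planar disk sampled on a jittered grid
.sampleDisk <- function(center, radius, normal, spacing) {
  g <- seq(-radius, radius, by = spacing)
  uv <- expand.grid(u = g, v = g)
  uv <- uv + matrix(stats::runif(2 * nrow(uv), -0.3, 0.3) * spacing, ncol = 2)
  uv <- uv[uv$u^2 + uv$v^2 <= radius^2, , drop = FALSE]
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  pts <- sweep(outer(uv$u, e1) + outer(uv$v, e2), 2, center, `+`)
  list(points = pts, normals = matrix(n, nrow(pts), 3, byrow = TRUE))
}

# open cylinder sampled on a jittered grid (axis must be unit length)
.sampleCylinder <- function(base, axis, length, radius, spacing) {
  nTheta <- max(4L, round(2 * pi * radius / spacing))
  nH <- max(2L, round(length / spacing))
  th <- rep(seq(0, 2 * pi, length.out = nTheta + 1)[-1], nH)
  h <- rep(seq(0, length, length.out = nH), each = nTheta)
  th <- th + stats::runif(length(th), -0.3, 0.3) * 2 * pi / nTheta
  h <- h + stats::runif(length(h), -0.3, 0.3) * length / nH
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    axis[2] * e1[3] - axis[3] * e1[2],
    axis[3] * e1[1] - axis[1] * e1[3],
    axis[1] * e1[2] - axis[2] * e1[1]
  )
  nrm <- outer(cos(th), e1) + outer(sin(th), e2)
  pts <- sweep(nrm * radius + outer(h, axis), 2, base, `+`)
  list(points = pts, normals = nrm)
}

#' Generate one grape bunch (berry centers and sampled surface)
#'
#' Berry centers are placed by sequential random insertion inside an
#' ellipsoidal bunch envelope: each new center must keep a center-to-center
#' distance of at least \code{r_i + r_j - overlap} to every placed berry
#' and at most \code{r_i + r_j + packingGap} to its nearest one, producing
#' the tight valley-ridge packing of a real bunch. Berry surfaces are
#' sampled at \code{spacing}; points falling strictly inside a neighboring
#' berry are removed and each surviving point is owned by its berry.
#'
#' @param nBerries number of berries (>= 1).
#' @param radiusMean,radiusSd berry radius distribution in meters
#'   (default 6 +/- 0.5 mm); radii are clamped to +/- 2 sd.
#' @param diameterRange alternative to the normal radius model: berry
#'   diameters drawn uniformly from this range (meters), as for an
#'   artificial reference bunch.
#' @param packingGap,overlap packing slack in meters (defaults 1.5 mm).
#' @param spacing surface sampling distance in meters (default 1 mm).
#' @param seed RNG seed (\code{NULL} = current RNG state).
#' @return list with \code{berries} (data.frame \code{x,y,z,r}),
#'   \code{points} (K x 3), \code{normals} (outward unit normals),
#'   \code{owner} (berry index per point).
#' @export
generateBunch <- function(nBerries, radiusMean = 0.006, radiusSd = 0.0005,
                          diameterRange = NULL,
                          packingGap = 0.0015, overlap = 0.0015,
                          spacing = 0.001, seed = NULL) {
  if (nBerries < 1) stop("nBerries must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  radii <- if (!is.null(diameterRange)) {
    stats::runif(nBerries, diameterRange[1], diameterRange[2]) / 2
  } else {
    pmin(pmax(stats::rnorm(nBerries, radiusMean, radiusSd),
              radiusMean - 2 * radiusSd), radiusMean + 2 * radiusSd)
  }
  rbar <- mean(radii)
  # ellipsoid envelope sized for ~30% packing fraction, elongated vertically
  a <- rbar * (nBerries / 0.48)^(1 / 3)
  ax <- c(a, a, 1.6 * a)

  centers <- matrix(0, nBerries, 3)
  for (i in seq_len(nBerries)) {
    placed <- FALSE
    for (try in seq_len(5000)) {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cand <- u * ax
      if (i == 1) { centers[i, ] <- cand; placed <- TRUE; break }
      d <- sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE], 2, cand)^2))
      sumr <- radii[seq_len(i - 1)] + radii[i]
      if (all(d >= sumr - overlap) && any(d <= sumr + packingGap)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible berry packing; loosen packingGap or shrink radii")
  }

  pts <- vector("list", nBerries)
  nrm <- vector("list", nBerries)
  own <- vector("list", nBerries)
  for (i in seq_len(nBerries)) {
    s <- .sampleSphere(centers[i, ], radii[i], spacing)
    keep <- rep(TRUE, nrow(s$points))
    for (j in seq_len(nBerries)) {
      if (j == i) next
      dj <- sqrt(rowSums(sweep(s$points, 2, centers[j, ])^2))
      keep <- keep & dj >= radii[j] - 0.3 * spacing
    }
    pts[[i]] <- s$points[keep, , drop = FALSE]
    nrm[[i]] <- s$normals[keep, , drop = FALSE]
    own[[i]] <- rep(i, sum(keep))
  }
  list(
    berries = data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                         r = radii),
    points = do.call(rbind, pts),
    normals = do.call(rbind, nrm),
    owner = unlist(own)
  )
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# per-class HSV color models; deliberately overlapping between bunch and
# canopy so neither color nor geometry alone separates the classes
.classColors <- function(n, class) {
  if (class == "bunch") {
    h <- stats::rnorm(n, 90, 20)
    s <- .clamp(stats::rnorm(n, 0.40, 0.10), 0.05, 1)
    v <- .clamp(stats::rnorm(n, 0.45, 0.10), 0.12, 1)
  } else if (class == "canopy") {
    h <- stats::rnorm(n, 110, 15)
    s <- .clamp(stats::rnorm(n, 0.60, 0.15), 0.05, 1)
    v <- .clamp(stats::rnorm(n, 0.55, 0.15), 0.12, 1)
  } else if (class == "background") {
    h <- stats::runif(n, 0, 360)
    s <- stats::runif(n, 0, 0.5)
    v <- stats::runif(n, 0.01, 0.07)
  } else {  # outliers: mid-brightness random colors (survive the V filter)
    h <- stats::runif(n, 0, 360)
    s <- stats::runif(n, 0.2, 0.8)
    v <- stats::runif(n, 0.2, 0.8)
  }
  hsvToRgb(cbind(h %% 360, s, v))
}

#' Scene generator configuration
#'
#' Defaults emulate the acquisition geometry of a camera rig driving along
#' a trellis row: camera distance 0.5-0.75 m from the row plane, ~15 cm
#' between consecutive positions, three camera heights, ~1 mm surface
#' sampling, berries of 6 +/- 0.5 mm radius.
#'
#' @param rowLength row extent along x in meters.
#' @param nBunches number of grape bunches.
#' @param berriesPerBunch integer range (min, max) of berries per bunch.
#' @param berryRadiusMean,berryRadiusSd berry radius model (meters).
#' @param bunchSpacing distance between bunch centers along the row
#'   (default \code{rowLength / nBunches}).
#' @param leafCount,leafRadius canopy leaf disks: count and radius.
#' @param stemCount,stemRadius,stemLength vertical stem cylinders
#'   (trunk/cordon scale by default, 12 mm radius: large enough that the
#'   9 mm histogram radius separates their curvature from berry
#'   curvature).
#' @param samplingSpacing surface sampling distance (default 1 mm).
#' @param noiseSigma surface noise standard deviation along the normal
#'   (default 0.2 mm).
#' @param outlierFraction,backgroundFraction fractions (of the surface
#'   point count) of uniform outliers and dark background points.
#' @param cameraDistance,cameraStep,cameraHeights camera track geometry.
#' @param seed RNG seed.
#' @return named list of class \code{"SceneConfig"}.
#' @export
sceneConfig <- function(rowLength = 2, nBunches = 8,
                        berriesPerBunch = c(8, 14),
                        berryRadiusMean = 0.006, berryRadiusSd = 0.0005,
                        bunchSpacing = rowLength / nBunches,
                        leafCount = 4 * nBunches, leafRadius = 0.015,
                        stemCount = 2, stemRadius = 0.012, stemLength = 0.15,
                        samplingSpacing = 0.001,
                        noiseSigma = 0.0002,
                        outlierFraction = 0.01, backgroundFraction = 0.05,
                        cameraDistance = 0.6, cameraStep = 0.15,
                        cameraHeights = c(0.9, 1.1, 1.3),
                        seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    rowLength > 0, nBunches >= 1, all(berriesPerBunch >= 1),
    berryRadiusMean > 0, samplingSpacing > 0, noiseSigma >= 0,
    outlierFraction >= 0, outlierFraction < 1,
    backgroundFraction >= 0, backgroundFraction < 1,
    cameraDistance > 0, cameraStep > 0
  )
  class(cfg) <- "SceneConfig"
  cfg
}

#' Generate a synthetic grapevine row scene
#'
#' Places grape bunches along the row at \code{bunchSpacing} (bunch zone
#' around z = 0.85 m), leaf disks and stem cylinders in the canopy above,
#' then emulates one-sided MVS coverage by keeping only points whose
#' outward normal faces at least one camera position (leaves, being thin,
#' are kept double-sided). Gaussian surface noise is applied along the
#' normals; uniform outliers and dark background points are appended.
#' Colors follow per-class HSV models that overlap between bunch and
#' canopy. Fully deterministic given \code{config$seed}.
#'
#' @param config a [sceneConfig()].
#' @return A [SyntheticScene-class].
#' @export
generateScene <- function(config = sceneConfig()) {
  stopifnot(inherits(config, "SceneConfig"))
  set.seed(config$seed)
  sp <- config$samplingSpacing

  pts <- list(); nrm <- list(); cls <- list(); bId <- list(); beId <- list()
  berryTables <- list()
  twoSided <- list()

  # grape bunches in the bunch zone
  nBerryTot <- 0L
  for (b in seq_len(config$nBunches)) {
    nb <- if (length(config$berriesPerBunch) > 1) {
      sample(config$berriesPerBunch[1]:config$berriesPerBunch[2], 1)
    } else config$berriesPerBunch
    bunch <- generateBunch(nb, config$berryRadiusMean, config$berryRadiusSd,
                           spacing = sp)
    ctr <- c((b - 0.5) * config$bunchSpacing + stats::runif(1, -0.1, 0.1) * config$bunchSpacing,
             stats::runif(1, -0.02, 0.02),
             0.85 + stats::runif(1, -0.04, 0.04))
    bunch$points <- sweep(bunch$points, 2, ctr, `+`)
    bt <- bunch$berries
    bt$x <- bt$x + ctr[1]; bt$y <- bt$y + ctr[2]; bt$z <- bt$z + ctr[3]
    bt$bunchId <- b
    bt$berryId <- nBerryTot + seq_len(nrow(bt))
    berryTables[[b]] <- bt
    k <- nrow(bunch$points)
    pts[[length(pts) + 1]] <- bunch$points
    nrm[[length(nrm) + 1]] <- bunch$normals
    cls[[length(cls) + 1]] <- rep("bunch", k)
    bId[[length(bId) + 1]] <- rep(b, k)
    beId[[length(beId) + 1]] <- nBerryTot + bunch$owner
    twoSided[[length(twoSided) + 1]] <- rep(FALSE, k)
    nBerryTot <- nBerryTot + nrow(bt)
  }

  # canopy: leaf disks
  for (l in seq_len(config$leafCount)) {
    ctr <- c(stats::runif(1, 0, config$rowLength),
             stats::runif(1, -0.05, 0.05),
             stats::runif(1, 1.05, 1.45))
    n0 <- c(stats::rnorm(1, 0, 0.3), -1, stats::rnorm(1, 0, 0.3))
    d <- .sampleDisk(ctr, config$leafRadius, n0, sp)
    k <- nrow(d$points)
    if (k == 0) next
    pts[[length(pts) + 1]] <- d$points
    nrm[[length(nrm) + 1]] <- d$normals
    cls[[length(cls) + 1]] <- rep("canopy", k)
    bId[[length(bId) + 1]] <- rep(NA_integer_, k)
    beId[[length(beId) + 1]] <- rep(NA_integer_, k)
    twoSided[[length(twoSided) + 1]] <- rep(TRUE, k)
  }

  # canopy: stems
  for (s in seq_len(config$stemCount)) {
    base <- c(stats::runif(1, 0.1, max(config$rowLength - 0.1, 0.1)),
              stats::runif(1, -0.02, 0.02), 1.05)
    cy <- .sampleCylinder(base, c(0, 0, 1), config$stemLength,
                          config$stemRadius, sp)
    k <- nrow(cy$points)
    pts[[length(pts) + 1]] <- cy$points
    nrm[[length(nrm) + 1]] <- cy$normals
    cls[[length(cls) + 1]] <- rep("canopy", k)
    bId[[length(bId) + 1]] <- rep(NA_integer_, k)
    beId[[length(beId) + 1]] <- rep(NA_integer_, k)
    twoSided[[length(twoSided) + 1]] <- rep(FALSE, k)
  }

  P <- do.call(rbind, pts)
  N <- do.call(rbind, nrm)
  cl <- unlist(cls)
  bunchId <- unlist(bId)
  berryId <- unlist(beId)
  two <- unlist(twoSided)

  cams <- as.matrix(expand.grid(
    x = seq(0, config$rowLength, by = config$cameraStep),
    y = -config$cameraDistance,
    z = config$cameraHeights
  ))
  dimnames(cams) <- NULL

  # visibility culling: keep points whose outward normal faces some camera
  visible <- two
  todo <- which(!two)
  if (length(todo)) {
    vis <- rep(FALSE, length(todo))
    for (m in seq_len(nrow(cams))) {
      dirs <- sweep(-P[todo, , drop = FALSE], 2, cams[m, ], `+`)  # cam - p
      vis <- vis | rowSums(N[todo, , drop = FALSE] * dirs) > 0
    }
    visible[todo] <- vis
  }
  P <- P[visible, , drop = FALSE]
  N <- N[visible, , drop = FALSE]
  cl <- cl[visible]; bunchId <- bunchId[visible]; berryId <- berryId[visible]

  # surface noise along the normal
  if (config$noiseSigma > 0) {
    P <- P + N * stats::rnorm(nrow(P), 0, config$noiseSigma)
  }

  nSurf <- nrow(P)
  # isolated outliers
  nOut <- round(config$outlierFraction * nSurf)
  if (nOut > 0) {
    lo <- apply(P, 2, min) - 0.05
    hi <- apply(P, 2, max) + 0.05
    O <- cbind(stats::runif(nOut, lo[1], hi[1]),
               stats::runif(nOut, lo[2], hi[2]),
               stats::runif(nOut, lo[3], hi[3]))
    P <- rbind(P, O)
    cl <- c(cl, rep("outlier", nOut))
    bunchId <- c(bunchId, rep(NA_integer_, nOut))
    berryId <- c(berryId, rep(NA_integer_, nOut))
  }
  # dark background points behind the row
  nBg <- round(config$backgroundFraction * nSurf)
  if (nBg > 0) {
    B <- cbind(stats::runif(nBg, 0, config$rowLength),
               stats::runif(nBg, 0.1, 0.5),
               stats::runif(nBg, 0.6, 1.5))
    P <- rbind(P, B)
    cl <- c(cl, rep("background", nBg))
    bunchId <- c(bunchId, rep(NA_integer_, nBg))
    berryId <- c(berryId, rep(NA_integer_, nBg))
  }

  colors <- matrix(0, nrow(P), 3)
  for (cc in unique(cl)) {
    i <- cl == cc
    colors[i, ] <- .classColors(sum(i), cc)
  }

  new("SyntheticScene",
    cloud = pointCloud(P, colors = colors),
    cameras = cameraTrack(cams),
    truth = data.frame(class = cl, bunchId = bunchId, berryId = berryId,
                       stringsAsFactors = FALSE),
    berries = do.call(rbind, berryTables),
    config = unclass(config)
  )
}

#' Generate a synthetic analog of an artificial reference grape bunch
#'
#' A single bunch with berry diameters drawn uniformly from
#' \code{diameterRange}, densely sampled at low noise — the kind of object
#' one would digitize with a close-range laser scanner to evaluate a berry
#' detector against caliper measurements. With \code{cull = TRUE} the rear
#' hemisphere (points whose normal faces away from every camera) is
#' removed, emulating a one-sided field reconstruction instead.
#'
#' @param nBerries number of berries (default 20).
#' @param diameterRange berry diameter range in meters (default 15-20 mm).
#' @param noiseSigma surface noise sd in meters (default 0.05 mm).
#' @param spacing sampling distance (default 0.5 mm).
#' @param cull cull points not facing any camera (default FALSE:
#'   all-around coverage).
#' @param cameraDistance distance of the synthetic camera track (0.6 m).
#' @param seed RNG seed.
#' @return A [SyntheticScene-class] containing the single bunch.
#' @export
generateArtificialBunch <- function(nBerries = 20,
                                    diameterRange = c(0.015, 0.020),
                                    noiseSigma = 5e-5, spacing = 5e-4,
                                    cull = FALSE, cameraDistance = 0.6,
                                    seed = 1L) {
  set.seed(seed)
  bunch <- generateBunch(nBerries, diameterRange = diameterRange,
                         spacing = spacing,
                         packingGap = 0.002, overlap = 0.002)
  P <- bunch$points
  N <- bunch$normals
  cams <- as.matrix(expand.grid(
    x = seq(-0.3, 0.3, by = 0.15), y = -cameraDistance, z = c(-0.1, 0, 0.1)
  ))
  dimnames(cams) <- NULL
  keep <- rep(TRUE, nrow(P))
  if (cull) {
    keep <- rep(FALSE, nrow(P))
    for (m in seq_len(nrow(cams))) {
      dirs <- sweep(-P, 2, cams[m, ], `+`)
      keep <- keep | rowSums(N * dirs) > 0
    }
  }
  P <- P[keep, , drop = FALSE]
  N <- N[keep, , drop = FALSE]
  owner <- bunch$owner[keep]
  if (noiseSigma > 0) P <- P + N * stats::rnorm(nrow(P), 0, noiseSigma)
  colors <- .classColors(nrow(P), "bunch")
  bt <- bunch$berries
  bt$bunchId <- 1L
  bt$berryId <- seq_len(nrow(bt))
  new("SyntheticScene",
    cloud = pointCloud(P, colors = colors),
    cameras = cameraTrack(cams),
    truth = data.frame(class = rep("bunch", nrow(P)), bunchId = 1L,
                       berryId = owner, stringsAsFactors = FALSE),
    berries = bt,
    config = list(nBerries = nBerries, diameterRange = diameterRange,
                  noiseSigma = noiseSigma, spacing = spacing, cull = cull,
                  seed = seed)
  )
}
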