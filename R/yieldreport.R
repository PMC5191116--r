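## Yield parameters and evaluation metrics.

# O(n^2 m) Hungarian algorithm with potentials (Jonker-Volgenant style).
# cost: n x m matrix with n <= m. Returns the cost-minimizing column
# assignment for each row (1-based). Index 1 of the working arrays plays
# the role of the virtual column; real column j lives at j + 1.
.hungarian <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)       # row potentials (u[i + 1] for row i, u[1] unused)
  v <- numeric(m + 1)       # column potentials (v[1] = virtual)
  p <- integer(m + 1)       # p[j]: row matched to column j - 1 (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      cur <- cost[i0, ] - u[i0 + 1] - v[2:(m + 1)]
      for (j in 2:(m + 1)) {
        if (used[j]) next
        if (cur[j - 1] < minv[j]) { minv[j] <- cur[j - 1]; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(m + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Final yield parameters from segmented components and detected berries
#'
#' Components in which fewer than \code{minBerries} berries were found are
#' rejected; the surviving component count is the grape bunch yield
#' parameter, and the berries pooled over survivors give the berry count
#' and diameter statistics. When the cloud is supplied, bunch and berry
#' counts are additionally binned per meter along the row axis (the first
#' principal axis of the coordinates).
#'
#' @param components list of components from [segmentBunches()].
#' @param berriesPerComponent list of berry data.frames (one per
#'   component, from [findBerries()]).
#' @param cloud optional [PointCloud-class] for the per-meter breakdown.
#' @param minBerries minimum berry count for a component to count as a
#'   grape bunch (default 3).
#' @return A [YieldReport-class].
#' @export
finalizeYield <- function(components, berriesPerComponent, cloud = NULL,
                          minBerries = 3) {
  if (minBerries < 1) stop("minBerries must be >= 1")
  if (length(components) != length(berriesPerComponent)) {
    stop("components and berriesPerComponent must align")
  }
  nBerries <- vapply(berriesPerComponent, nrow, 1L)
  retained <- nBerries >= minBerries
  diameters <- unlist(lapply(berriesPerComponent[retained],
                             function(b) b$diameter), use.names = FALSE)
  if (is.null(diameters)) diameters <- numeric(0)

  perMeter <- data.frame()
  if (!is.null(cloud) && any(retained) && nPoints(cloud) > 1) {
    xyz <- coords(cloud)
    axis1 <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)$rotation[, 1]
    proj <- drop(xyz %*% axis1)
    centroids <- vapply(components[retained], function(cp) {
      mean(proj[cp$indices])
    }, 1.0)
    bin <- floor(centroids - min(proj))
    perMeter <- as.data.frame(table(meter = bin + 1))
    names(perMeter) <- c("meter", "bunches")
    perMeter$meter <- as.integer(as.character(perMeter$meter))
  }

  new("YieldReport",
    bunchCount = sum(retained),
    berryCount = as.integer(sum(nBerries[retained])),
    diameters = as.numeric(diameters),
    diameterMean = if (length(diameters)) mean(diameters) else NA_real_,
    diameterSd = if (length(diameters) > 1) stats::sd(diameters) else NA_real_,
    componentBerries = berriesPerComponent,
    retained = retained,
    perMeter = perMeter
  )
}

#' Score predicted bunch components against reference bunches
#'
#' Greedy one-to-one matching by maximum point overlap: the
#' largest-overlap (component, reference) pairs are matched first, each
#' component and each reference at most once. Matched pairs are true
#' positives; unmatched references are false negatives (so a component
#' fusing k true bunches contributes k - 1 false negatives); unmatched
#' components are false positives (so a bunch split into two components
#' contributes one true positive and one false positive).
#'
#' @param predicted list of components (each with an \code{indices}
#'   element) or a plain list of integer index vectors.
#' @param reference list of reference bunch point index vectors, or an
#'   integer vector mapping each point to a reference bunch id (NA =
#'   no bunch).
#' @return An [EvalResult-class].
#' @export
scoreBunches <- function(predicted, reference) {
  predIdx <- lapply(predicted, function(cp) {
    if (is.list(cp)) as.integer(cp$indices) else as.integer(cp)
  })
  if (!is.list(reference)) {
    ids <- reference
    refIdx <- lapply(
      sort(unique(ids[!is.na(ids)])),
      function(b) which(!is.na(ids) & ids == b)
    )
  } else {
    refIdx <- lapply(reference, as.integer)
  }
  nP <- length(predIdx)
  nR <- length(refIdx)
  if (nP == 0 || nR == 0) {
    return(.evalResult(0L, nP, nR))
  }
  ov <- matrix(0L, nP, nR)
  for (a in seq_len(nP)) {
    for (b in seq_len(nR)) {
      ov[a, b] <- length(intersect(predIdx[[a]], refIdx[[b]]))
    }
  }
  matchedP <- logical(nP)
  matchedR <- logical(nR)
  tp <- 0L
  repeat {
    ov[matchedP, ] <- -1L
    ov[, matchedR] <- -1L
    best <- which.max(ov)
    if (ov[best] <= 0) break
    a <- (best - 1) %% nP + 1
    b <- (best - 1) %/% nP + 1
    matchedP[a] <- TRUE
    matchedR[b] <- TRUE
    tp <- tp + 1L
  }
  .evalResult(tp, fp = sum(!matchedP), fn = sum(!matchedR))
}

#' Score detected berries against reference berries
#'
#' Optimal one-to-one assignment (Hungarian algorithm) between predicted
#' and reference berry centers under a distance cap: pairs farther apart
#' than \code{matchDist} cannot match. Matched pairs are true positives;
#' surplus detections are false positives; unmatched references are false
#' negatives. The RMSE of the matched diameters is reported alongside.
#'
#' @param predicted data.frame with columns \code{x,y,z} and
#'   \code{diameter} (e.g. from [findBerries()]).
#' @param reference data.frame with columns \code{x,y,z} and
#'   \code{diameter} (true berries; the \code{r} column of a
#'   [sceneBerries()] table is accepted and doubled).
#' @param matchDist maximum center distance for a match (meters).
#' @return An [EvalResult-class] (RMSE in meters).
#' @export
scoreBerries <- function(predicted, reference, matchDist = 0.012) {
  if (!is.numeric(matchDist) || matchDist <= 0) stop("matchDist must be > 0")
  pred <- as.data.frame(predicted)
  ref <- as.data.frame(reference)
  if (is.null(ref$diameter) && !is.null(ref$r)) ref$diameter <- 2 * ref$r
  nP <- nrow(pred)
  nR <- nrow(ref)
  if (nP == 0 || nR == 0) {
    return(.evalResult(0L, nP, nR))
  }
  pc <- as.matrix(pred[, c("x", "y", "z")])
  rc <- as.matrix(ref[, c("x", "y", "z")])
  D <- sqrt(pmax(outer(rowSums(pc^2), rowSums(rc^2), `+`) -
                   2 * tcrossprod(pc, rc), 0))
  BIG <- 1e6
  Dcap <- ifelse(D <= matchDist, D, BIG)
  flip <- nP > nR
  asg <- if (flip) .hungarian(t(Dcap)) else .hungarian(Dcap)
  pairs <- if (flip) cbind(asg, seq_len(nR)) else cbind(seq_len(nP), asg)
  okPair <- D[pairs] <= matchDist
  tp <- sum(okPair)
  rmse <- NA_real_
  if (tp > 0) {
    dd <- pred$diameter[pairs[okPair, 1]] - ref$diameter[pairs[okPair, 2]]
    rmse <- sqrt(mean(dd^2))
  }
  .evalResult(tp, fp = nP - tp, fn = nR - tp, rmse = rmse)
}
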