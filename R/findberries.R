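#' Least-squares sphere fit
#'
#' Algebraic fit by the linearization \code{||p||^2 = 2 c . p + (r^2 -
#' ||c||^2)}, followed by one Gauss-Newton refinement step on the geometric
#' residuals \code{||p_i - c|| - r}.
#'
#' @param points K x 3 coordinate matrix, K >= 4, not coplanar.
#' @return list with \code{center} (3-vector), \code{radius} and
#'   \code{rms} (root mean square of the geometric residuals).
#' @export
fitSphere <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qrA <- qr(A)
  if (qrA$rank < 4) stop("degenerate sphere fit: points are coplanar")
  sol <- qr.coef(qrA, b)
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) stop("degenerate sphere fit")
  r <- sqrt(r2)
  # one Gauss-Newton step on (center, radius)
  d <- sweep(P, 2, ctr)
  dn <- sqrt(rowSums(d^2))
  ok <- dn > 1e-12
  if (sum(ok) >= 4) {
    J <- cbind(-d[ok, , drop = FALSE] / dn[ok], -1)
    e <- dn[ok] - r
    step <- tryCatch(qr.solve(J, -e), error = function(err) rep(0, 4))
    ctr <- ctr + step[1:3]
    r <- r + step[4]
    d <- sweep(P, 2, ctr)
    dn <- sqrt(rowSums(d^2))
  }
  if (!is.finite(r) || r <= 0) stop("degenerate sphere fit")
  list(center = unname(ctr), radius = unname(r),
       rms = sqrt(mean((dn - r)^2)))
}

.sphereOverlap <- function(cA, rA, cB, rB) {
  d <- sqrt(sum((cA - cB)^2))
  max(0, (rA + rB - d) / (2 * min(rA, rB)))
}

#' Evaluate a sphere candidate against the berry acceptance hierarchy
#'
#' The four checks are applied strictly in order, reporting the first
#' failure:
#' \enumerate{
#'   \item \emph{radius}: the radius must lie in \[\code{rMin},
#'     \code{rMax}\].
#'   \item \emph{support}: among the points the (10\%-inflated) sphere
#'     encompasses, those within \code{inlierTol * radius} of the surface
#'     are inliers; the inlier fraction must reach \code{minSupportRatio}
#'     and the inlier count \code{minFitPoints}.
#'   \item \emph{valley}: a segment is drawn from the center toward the
#'     nearest camera (length \code{radius + lineTol}); at least
#'     \code{minLinePoints} cloud points must lie within \code{lineTol}
#'     of it (the berry's crown). A sphere wedged in the space between
#'     berries has no points there and is rejected.
#'   \item \emph{overlap}: against already accepted berries, the overlap
#'     ratio \code{max(0, (rA + rB - ||cA - cB||) / (2 min(rA, rB)))} may
#'     not exceed \code{overlapRatio} — unless the candidate's support is
#'     strictly larger than that of every overlapped berry, in which case
#'     the candidate wins and the overlapped berries are evicted.
#' }
#'
#' @param sphere list with \code{center} and \code{radius} (from
#'   [fitSphere()]).
#' @param xyz K x 3 coordinates of the (remaining) component points that
#'   can support the candidate.
#' @param cameras a [CameraTrack-class].
#' @param params a [pipelineConfig()] (the berry-related entries are used).
#' @param accepted optional data.frame of already accepted berries with
#'   columns \code{x,y,z,r,support}.
#' @return list with \code{verdict} ("accept" or "reject"), \code{reason}
#'   (NA, "radius", "support", "valley" or "overlap"), \code{support}
#'   (indices into \code{xyz} rows), \code{nLine}, and \code{evict}
#'   (row indices of \code{accepted} to drop when the candidate wins an
#'   overlap contest).
#' @export
evaluateBerryCandidate <- function(sphere, xyz, cameras, params = pipelineConfig(),
                                   accepted = NULL) {
  ctr <- sphere$center
  r <- sphere$radius
  # (1) radius range
  if (r < params$rMin || r > params$rMax) {
    return(list(verdict = "reject", reason = "radius", support = integer(0),
                nLine = 0L, evict = integer(0)))
  }
  xyz <- as.matrix(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  near <- which(d <= r * (1 + params$inlierTol))
  inl <- near[abs(d[near] - r) <= params$inlierTol * r]
  # (2) outlier-inlier ratio + minimum support
  if (length(inl) < params$minFitPoints ||
      length(inl) / max(length(near), 1L) < params$minSupportRatio) {
    return(list(verdict = "reject", reason = "support", support = inl,
                nLine = 0L, evict = integer(0)))
  }
  # (3) valley test: points near the center-to-camera segment. A sphere on
  # a berry has its crown there; a sphere wedged in the gap between
  # berries has nothing in front of it. All nearby cloud points count, not
  # only the inlier shell.
  cams <- cameraPositions(cameras)
  ci <- which.min(colSums((t(cams) - ctr)^2))
  dir <- cams[ci, ] - ctr
  dir <- dir / sqrt(sum(dir^2))
  tube <- which(d <= r + 2 * params$lineTol)
  rel <- sweep(xyz[tube, , drop = FALSE], 2, ctr)
  tproj <- drop(rel %*% dir)
  perp2 <- rowSums(rel^2) - tproj^2
  onLine <- tproj >= 0 & tproj <= r + params$lineTol &
    perp2 <= params$lineTol^2
  if (sum(onLine) < params$minLinePoints) {
    return(list(verdict = "reject", reason = "valley", support = inl,
                nLine = as.integer(sum(onLine)), evict = integer(0)))
  }
  # (4) overlap with accepted berries
  evict <- integer(0)
  if (!is.null(accepted) && nrow(accepted) > 0) {
    ov <- vapply(seq_len(nrow(accepted)), function(j) {
      .sphereOverlap(ctr, r,
                     c(accepted$x[j], accepted$y[j], accepted$z[j]),
                     accepted$r[j])
    }, 1.0)
    clash <- which(ov > params$overlapRatio)
    if (length(clash)) {
      if (all(accepted$support[clash] < length(inl))) {
        evict <- clash
      } else {
        return(list(verdict = "reject", reason = "overlap", support = inl,
                    nLine = as.integer(sum(onLine)), evict = integer(0)))
      }
    }
  }
  list(verdict = "accept", reason = NA_character_, support = inl,
       nLine = as.integer(sum(onLine)), evict = evict)
}

#' Detect berries in a grape bunch component by randomized sphere fitting
#'
#' Repeatedly draws a random source point from the remaining points of the
#' component, fits a sphere to its \code{fitRadiusFactor * rMax}
#' neighborhood, and runs the candidate through the four-stage acceptance
#' hierarchy of [evaluateBerryCandidate()]. On acceptance the support
#' points are removed from the remaining set and the failure counter
#' resets; berries evicted in an overlap contest return their support to
#' the pool. The loop stops when the number of consecutive failures
#' reaches twice the current remaining point count, or too few points
#' remain for a fit.
#'
#' @param xyz K x 3 coordinates of one bunch component (meters).
#' @param cameras a [CameraTrack-class].
#' @param params a [pipelineConfig()].
#' @param seed RNG seed; \code{NULL} uses the current RNG state.
#' @return data.frame of accepted berries sorted by decreasing support:
#'   columns \code{x,y,z} (center), \code{r} (radius), \code{diameter},
#'   \code{support} (inlier count), \code{rms}; the support index sets
#'   (into the rows of \code{xyz}) are attached as the
#'   \code{"supportIndices"} attribute (pairwise disjoint).
#' @export
findBerries <- function(xyz, cameras, params = pipelineConfig(), seed = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) == 0) stop("empty component")
  if (!is.null(seed)) set.seed(seed)
  fitRadius <- params$fitRadiusFactor * params$rMax

  n <- nrow(xyz)
  remaining <- rep(1L, n)
  nRemaining <- n
  grid <- .cppGridBuild(xyz, fitRadius)

  berries <- list()
  failures <- 0L
  while (nRemaining >= params$minFitPoints &&
         failures < 2L * nRemaining) {
    # uniform draw over the remaining set by rejection (cheap while the
    # remaining fraction is not tiny, which the stopping rule guarantees)
    repeat {
      src <- sample.int(n, 1L)
      if (remaining[src]) break
    }
    nb <- .cppGridQuery(grid, xyz[src, ], fitRadius, remaining)
    ok <- length(nb) >= params$minFitPoints
    verdict <- NULL
    if (ok) {
      # initial fit on the local patch around the source (within rMin, so
      # it is almost surely a single berry's surface), falling back to the
      # full neighborhood when the patch is too small or degenerate
      nbXyz <- xyz[nb, , drop = FALSE]
      d2src <- rowSums(sweep(nbXyz, 2, xyz[src, ])^2)
      patch <- which(d2src <= params$rMin^2)
      sphere <- NULL
      if (length(patch) >= params$minFitPoints) {
        sphere <- tryCatch(fitSphere(nbXyz[patch, , drop = FALSE]),
                           error = function(e) NULL)
      }
      if (is.null(sphere)) {
        sphere <- tryCatch(fitSphere(nbXyz), error = function(e) NULL)
      }
      # refine on the inlier shell so the accepted sphere does not depend
      # on which source point seeded it
      if (!is.null(sphere)) {
        for (it in 1:3) {
          if (sphere$radius < 0.5 * params$rMin ||
              sphere$radius > 2 * params$rMax) break
          shell <- .cppGridQuery(grid, sphere$center,
                                 sphere$radius * (1 + params$inlierTol),
                                 remaining)
          if (length(shell) < params$minFitPoints) break
          d <- sqrt(rowSums(sweep(xyz[shell, , drop = FALSE], 2,
                                  sphere$center)^2))
          inl <- shell[abs(d - sphere$radius) <=
                         params$inlierTol * sphere$radius]
          if (length(inl) < params$minFitPoints) break
          refit <- tryCatch(fitSphere(xyz[inl, , drop = FALSE]),
                            error = function(e) NULL)
          if (is.null(refit)) break
          moved <- sqrt(sum((refit$center - sphere$center)^2))
          sphere <- refit
          if (moved < 1e-5) break
        }
      }
      if (!is.null(sphere)) {
        verdict <- .evalCandidateGrid(sphere, xyz, grid, remaining, cameras,
                                      params, berries)
      }
    }
    if (!is.null(verdict) && verdict$verdict == "accept") {
      if (length(verdict$evict)) {
        for (j in verdict$evict) {
          remaining[berries[[j]]$support] <- 1L
          nRemaining <- nRemaining + length(berries[[j]]$support)
        }
        berries <- berries[-verdict$evict]
      }
      berries[[length(berries) + 1]] <- list(
        center = verdict$sphere$center, r = verdict$sphere$radius,
        rms = verdict$sphere$rms, support = verdict$support
      )
      remaining[verdict$support] <- 0L
      nRemaining <- nRemaining - length(verdict$support)
      failures <- 0L
    } else {
      failures <- failures + 1L
    }
  }

  if (!length(berries)) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      r = numeric(0), diameter = numeric(0),
                      support = integer(0), rms = numeric(0))
    attr(out, "supportIndices") <- list()
    return(out)
  }
  ord <- order(vapply(berries, function(b) length(b$support), 1L),
               decreasing = TRUE)
  berries <- berries[ord]
  ctr <- t(vapply(berries, `[[`, numeric(3), "center"))
  out <- data.frame(
    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
    r = vapply(berries, `[[`, 1.0, "r"),
    support = vapply(berries, function(b) length(b$support), 1L),
    rms = vapply(berries, `[[`, 1.0, "rms")
  )
  out$diameter <- 2 * out$r
  out <- out[, c("x", "y", "z", "r", "diameter", "support", "rms")]
  attr(out, "supportIndices") <- lapply(berries, `[[`, "support")
  out
}

# grid-accelerated variant of evaluateBerryCandidate used in the hot loop;
# identical checks, support restricted to remaining points
.evalCandidateGrid <- function(sphere, xyz, grid, remaining, cameras, params,
                               berries) {
  ctr <- sphere$center
  r <- sphere$radius
  if (r < params$rMin || r > params$rMax) {
    return(list(verdict = "reject", reason = "radius"))
  }
  near <- .cppGridQuery(grid, ctr, r * (1 + params$inlierTol), remaining)
  if (!length(near)) return(list(verdict = "reject", reason = "support"))
  d <- sqrt(rowSums(sweep(xyz[near, , drop = FALSE], 2, ctr)^2))
  inl <- near[abs(d - r) <= params$inlierTol * r]
  if (length(inl) < params$minFitPoints ||
      length(inl) / length(near) < params$minSupportRatio) {
    return(list(verdict = "reject", reason = "support"))
  }
  cams <- cameraPositions(cameras)
  ci <- which.min(colSums((t(cams) - ctr)^2))
  dir <- cams[ci, ] - ctr
  dir <- dir / sqrt(sum(dir^2))
  tube <- .cppGridQuery(grid, ctr, r + 2 * params$lineTol, remaining)
  rel <- sweep(xyz[tube, , drop = FALSE], 2, ctr)
  tproj <- drop(rel %*% dir)
  perp2 <- rowSums(rel^2) - tproj^2
  nLine <- sum(tproj >= 0 & tproj <= r + params$lineTol &
                 perp2 <= params$lineTol^2)
  if (nLine < params$minLinePoints) {
    return(list(verdict = "reject", reason = "valley"))
  }
  evict <- integer(0)
  if (length(berries)) {
    ov <- vapply(berries, function(b) {
      .sphereOverlap(ctr, r, b$center, b$r)
    }, 1.0)
    clash <- which(ov > params$overlapRatio)
    if (length(clash)) {
      supClash <- vapply(berries[clash], function(b) length(b$support), 1L)
      if (all(supClash < length(inl))) {
        evict <- clash
      } else {
        return(list(verdict = "reject", reason = "overlap"))
      }
    }
  }
  list(verdict = "accept", reason = NA_character_, support = inl,
       sphere = sphere, evict = evict)
}
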