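#' Connected components at a distance threshold
#'
#' Single-linkage partition: two points share a component iff they are
#' connected by a chain of hops each no longer than \code{dist}.
#' Implemented with grid-bucketed union-find; deterministic (ids numbered
#' by first appearance in point order).
#'
#' @param x a [PointCloud-class] or N x 3 coordinate matrix.
#' @param dist hop distance threshold in meters.
#' @return integer vector of component ids (1-based).
#' @export
connectedComponents <- function(x, dist) {
  xyz <- if (is(x, "PointCloud")) coords(x) else as.matrix(x)
  if (!is.numeric(dist) || dist <= 0) stop("dist must be > 0")
  if (nrow(xyz) == 0) return(integer(0))
  .cppConnectedComponents(xyz, dist)
}

.componentsFromIds <- function(ids, indices, stage) {
  lapply(split(indices, ids), function(ix) {
    list(indices = as.integer(ix), stage = stage)
  })
}

#' Delete undersized components
#'
#' @param components list of components (each with an \code{indices}
#'   element), e.g. from [segmentBunches()].
#' @param minPoints minimum component size to survive.
#' @return list with \code{components} (survivors) and \code{deleted}.
#' @export
filterSmall <- function(components, minPoints) {
  if (minPoints < 1) stop("minPoints must be >= 1")
  sizes <- vapply(components, function(cp) length(cp$indices), 1L)
  keep <- sizes >= minPoints
  list(components = components[keep], deleted = components[!keep])
}

#' Split oversized components with a tighter distance threshold
#'
#' Components larger than \code{maxPoints} usually mean several grape
#' bunches fused into one region; they are re-partitioned by connected
#' components at the smaller threshold \code{ccDist2}, and fragments that
#' fall below \code{minPoints} after the split are discarded.
#'
#' @param components list of components.
#' @param xyz N x 3 coordinate matrix the component indices refer to.
#' @param maxPoints size above which a component is re-split.
#' @param ccDist2 split distance threshold (meters), smaller than the
#'   first-pass threshold.
#' @param minPoints re-filter threshold applied to split fragments.
#' @return list with \code{components} and \code{deleted} (fragments
#'   removed by the re-filter).
#' @export
splitLarge <- function(components, xyz, maxPoints, ccDist2, minPoints = 1) {
  out <- list()
  deleted <- list()
  for (cp in components) {
    if (length(cp$indices) <= maxPoints) {
      out[[length(out) + 1]] <- cp
      next
    }
    ids <- connectedComponents(xyz[cp$indices, , drop = FALSE], ccDist2)
    frags <- .componentsFromIds(ids, cp$indices, "split")
    flt <- filterSmall(frags, minPoints)
    out <- c(out, flt$components)
    deleted <- c(deleted, flt$deleted)
  }
  list(components = unname(out), deleted = unname(deleted))
}

#' Segment grape-bunch points into candidate bunch components
#'
#' Two-stage connected components over the points labeled as grape bunch:
#' a first pass at \code{ccDist1} (~5 mm), deletion of components below
#' \code{minPoints} (classification noise), then re-splitting of
#' components above \code{maxPoints} (fused bunches) at \code{ccDist2}
#' (~1 mm) with the size filter re-applied to the fragments.
#'
#' @param cloud a labeled [PointCloud-class] (labels 0/1; see
#'   [smoothLabels()]).
#' @param config a [pipelineConfig()].
#' @return list with \code{components} (each a list with global point
#'   \code{indices} and \code{stage}) and \code{deleted}.
#' @export
segmentBunches <- function(cloud, config = pipelineConfig()) {
  stopifnot(is(cloud, "PointCloud"))
  labels <- pointLabels(cloud)
  if (is.null(labels)) stop("segmentBunches needs labels")
  bunchIdx <- which(labels == 1L)
  if (!length(bunchIdx)) return(list(components = list(), deleted = list()))
  xyz <- coords(cloud)
  ids <- connectedComponents(xyz[bunchIdx, , drop = FALSE], config$ccDist1)
  comps <- .componentsFromIds(ids, bunchIdx, "first")
  flt <- filterSmall(comps, config$minPoints)
  spl <- splitLarge(flt$components, xyz, config$maxPoints, config$ccDist2,
                    config$minPoints)
  list(
    components = unname(spl$components),
    deleted = unname(c(flt$deleted, spl$deleted))
  )
}
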