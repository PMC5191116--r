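#' Build the radius neighbor graph
#'
#' Edges connect every pair of points within \code{radius} of each other
#' (no self loops, each unordered pair once).
#'
#' @param cloud a [PointCloud-class] or an N x 3 coordinate matrix.
#' @param radius connection radius in meters (default 3 mm, about three
#'   times the subsampling distance).
#' @return list of class \code{"NeighborGraph"} with \code{edges} (E x 2
#'   integer matrix, first column < second), \code{radius} and \code{n}.
#' @export
buildNeighborGraph <- function(cloud, radius = 0.003) {
  xyz <- if (is(cloud, "PointCloud")) coords(cloud) else as.matrix(cloud)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  edges <- .cppRadiusEdges(xyz, radius)
  structure(
    list(edges = edges, radius = radius, n = nrow(xyz)),
    class = "NeighborGraph"
  )
}

#' Energy of a labeling
#'
#' The objective minimized by [smoothLabels()]:
#' \code{sum_i (1 - P_i(L_i)) + penalty * #\{(i,j) in edges : L_i != L_j\}}.
#'
#' @param posteriors N x 2 posterior matrix.
#' @param graph a \code{"NeighborGraph"} from [buildNeighborGraph()].
#' @param penalty Potts penalty (>= 0).
#' @param labels integer labels in \{0, 1\}.
#' @return The scalar energy.
#' @export
labelingEnergy <- function(posteriors, graph, penalty, labels) {
  p <- as.matrix(posteriors)
  unary <- sum(1 - p[cbind(seq_len(nrow(p)), labels + 1L)])
  e <- graph$edges
  pairwise <- if (nrow(e)) sum(labels[e[, 1]] != labels[e[, 2]]) else 0
  unary + penalty * pairwise
}

#' Smooth class labels by exact graph-cut energy minimization
#'
#' Finds the global minimizer of the binary Potts energy whose unary cost
#' at point i for label l is \code{1 - P_i(l)} (the complement of the
#' classifier's posterior) and whose pairwise cost is \code{penalty} for
#' every neighbor-graph edge with diverging labels. For two labels this
#' energy is submodular, so a single s-t max-flow / min-cut computation
#' (Dinic's algorithm) yields the exact optimum.
#'
#' @param posteriors N x 2 matrix of class posteriors from [predictIVM()].
#' @param graph a \code{"NeighborGraph"} over the same points.
#' @param penalty Potts penalty for diverging labels (>= 0; default 0.5).
#' @return list with \code{labels} (integer, \{0, 1\}), \code{energy}
#'   (achieved, i.e. minimal), and \code{energyInitial} (energy of the
#'   argmax labeling).
#' @export
smoothLabels <- function(posteriors, graph, penalty = 0.5) {
  posteriors <- as.matrix(posteriors)
  if (ncol(posteriors) != 2) stop("posteriors must be N x 2")
  if (!is.numeric(penalty) || penalty < 0) stop("penalty must be >= 0")
  n <- nrow(posteriors)
  if (graph$n != n) stop("graph and posteriors disagree on N")
  argmax <- assignLabels(posteriors)
  energyInitial <- labelingEnergy(posteriors, graph, penalty, argmax)
  if (penalty == 0 || n == 0) {
    return(list(labels = argmax, energy = energyInitial,
                energyInitial = energyInitial))
  }

  u0 <- 1 - posteriors[, 1]  # cost of label 0 (canopy)
  u1 <- 1 - posteriors[, 2]  # cost of label 1 (bunch)
  # s-t construction: source side = label 1. After subtracting the
  # constant min(u0, u1) per node, each node keeps a single terminal edge:
  # i->t with u1 - u0 when label 1 is the costlier choice, s->i with
  # u0 - u1 otherwise. Each neighbor edge carries `penalty` both ways.
  labels <- .cppMinCutPotts(n, graph$edges, penalty,
                            pmax(u0 - u1, 0), pmax(u1 - u0, 0))
  energy <- labelingEnergy(posteriors, graph, penalty, labels)
  list(labels = labels, energy = energy, energyInitial = energyInitial)
}
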