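# Brute-force oracles used to validate the grid-accelerated kernels, plus
# small fixture builders. All O(N^2) and intended for small N only.

bruteMeanKnnDist <- function(xyz, k) {
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  unname(apply(d, 1, function(row) mean(sort(row)[seq_len(k)])))
}

bruteRadiusEdges <- function(xyz, radius) {
  d <- as.matrix(dist(xyz))
  idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# connected components through igraph (independent of the union-find code)
bruteComponents <- function(xyz, dist) {
  n <- nrow(xyz)
  adj <- as.matrix(stats::dist(xyz)) <= dist
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

samePartition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}

bruteAssignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, m <= 7)
  best <- Inf
  bestAsg <- NULL
  rec <- function(row, used, asg, acc) {
    if (acc >= best) return()
    if (row > n) {
      best <<- acc
      bestAsg <<- asg
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(row + 1, used, c(asg, j), acc + cost[row, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), integer(0), 0)
  list(cost = best, assignment = bestAsg)
}

# exhaustive minimum of the binary Potts energy (vectorized over labelings)
bruteMinEnergy <- function(posteriors, graph, penalty) {
  n <- nrow(posteriors)
  stopifnot(n <= 15)
  bits <- t(as.matrix(expand.grid(rep(list(0:1), n))))
  u0 <- 1 - posteriors[, 1]
  u1 <- 1 - posteriors[, 2]
  en <- sum(u0) + drop(crossprod(bits, u1 - u0))
  e <- graph$edges
  if (nrow(e)) {
    en <- en + penalty * colSums(bits[e[, 1], , drop = FALSE] !=
                                   bits[e[, 2], , drop = FALSE])
  }
  min(en)
}

# independent scalar RGB -> HSV (per-element hexcone, no vectorization)
scalarRgbToHsv <- function(r, g, b) {
  mx <- max(r, g, b)
  mn <- min(r, g, b)
  d <- mx - mn
  h <- if (d == 0) 0
  else if (mx == r) 60 * (((g - b) / d) %% 6)
  else if (mx == g) 60 * ((b - r) / d + 2)
  else 60 * ((r - g) / d + 4)
  c(h %% 360, if (mx > 0) d / mx else 0, mx)
}

# independent R implementation of the pairwise Darboux-frame features and
# the joint 125-bin histogram for one query point
bruteSfhPoint <- function(xyz, normals, i, rH) {
  d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  nb <- which(d <= rH & !is.na(normals[, 1]))
  if (length(nb) < 3) return(rep(0, 125))
  h <- rep(0, 125)
  for (a in seq_along(nb)) {
    for (b in seq_along(nb)) {
      if (b <= a) next
      p1 <- xyz[nb[a], ]; n1 <- normals[nb[a], ]
      p2 <- xyz[nb[b], ]; n2 <- normals[nb[b], ]
      dv <- p2 - p1
      dn <- sqrt(sum(dv^2))
      if (dn < 1e-12) next
      dd <- dv / dn
      if (sum(n1 * dd) >= sum(n2 * -dd)) {
        u <- n1; nt <- n2
      } else {
        u <- n2; nt <- n1; dd <- -dd
      }
      v <- c(dd[2] * u[3] - dd[3] * u[2],
             dd[3] * u[1] - dd[1] * u[3],
             dd[1] * u[2] - dd[2] * u[1])
      vn <- sqrt(sum(v^2))
      v <- if (vn < 1e-12) c(0, 0, 0) else v / vn
      w <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      f1 <- sum(v * nt)
      f2 <- sum(u * dd)
      f3 <- atan2(sum(w * nt), sum(u * nt))
      b1 <- min(max(floor((f1 + 1) / 2 * 5), 0), 4)
      b2 <- min(max(floor((f2 + 1) / 2 * 5), 0), 4)
      b3 <- min(max(floor((f3 + pi) / (2 * pi) * 5), 0), 4)
      h[b1 * 25 + b2 * 5 + b3 + 1] <- h[b1 * 25 + b2 * 5 + b3 + 1] + 1
    }
  }
  if (sum(h) > 0) h / sum(h) else h
}

randomRotation3 <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# evenly sampled sphere surface points (not via the package generator)
sphereFixture <- function(center = c(0, 0, 0), r = 0.006, n = 500) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(1 - z^2, 0))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  sweep(dirs * r, 2, center, `+`)
}

planeFixture <- function(extent = 0.02, spacing = 5e-4, z = 0) {
  g <- seq(0, extent, by = spacing)
  as.matrix(cbind(expand.grid(g, g), z))
}
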