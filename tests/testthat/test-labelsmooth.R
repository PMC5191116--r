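test_that("neighbor graph edges match the brute-force pair scan", {
  two <- matrix(c(0, 0, 0, 0.006, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(buildNeighborGraph(two, 0.003)$edges), 0)

  three <- matrix(c(0, 0, 0, 0.003, 0, 0, 0.006, 0, 0), 3, 3, byrow = TRUE)
  g3 <- buildNeighborGraph(three, 0.003)
  expect_equal(nrow(g3$edges), 2)

  set.seed(13)
  xyz <- matrix(runif(1500, 0, 0.03), ncol = 3)
  g <- buildNeighborGraph(xyz, 0.004)
  ref <- bruteRadiusEdges(xyz, 0.004)
  got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(ref), ignore_attr = TRUE)
})

test_that("penalty 0 reduces to argmax; huge penalty forces a uniform labeling", {
  set.seed(14)
  n <- 40
  p1 <- runif(n)
  post <- cbind(1 - p1, p1)
  xyz <- matrix(runif(3 * n, 0, 0.01), ncol = 3)
  g <- buildNeighborGraph(xyz, 0.004)

  res0 <- smoothLabels(post, g, 0)
  expect_identical(res0$labels, assignLabels(post))

  resInf <- smoothLabels(post, g, n)
  expect_equal(length(unique(resInf$labels)), 1)
  u <- c(sum(1 - post[, 1]), sum(1 - post[, 2]))
  expect_identical(unique(resInf$labels), as.integer(which.min(u) - 1))
})

test_that("graph-cut labeling achieves the exhaustive minimum energy", {
  set.seed(15)
  for (t in 1:40) {
    n <- sample(4:12, 1)
    p1 <- runif(n)
    post <- cbind(1 - p1, p1)
    xyz <- matrix(runif(3 * n, 0, 0.01), ncol = 3)
    g <- buildNeighborGraph(xyz, 0.004)
    pen <- runif(1, 0, 1)
    res <- smoothLabels(post, g, pen)
    expect_equal(res$energy, bruteMinEnergy(post, g, pen), tolerance = 1e-9)
    expect_lte(res$energy, res$energyInitial + 1e-12)
  }
})

test_that("smoothing is permutation invariant up to energy equality", {
  set.seed(16)
  n <- 60
  p1 <- runif(n)
  post <- cbind(1 - p1, p1)
  xyz <- matrix(runif(3 * n, 0, 0.012), ncol = 3)
  g <- buildNeighborGraph(xyz, 0.005)
  res <- smoothLabels(post, g, 0.5)
  perm <- sample(n)
  g2 <- buildNeighborGraph(xyz[perm, ], 0.005)
  res2 <- smoothLabels(post[perm, ], g2, 0.5)
  expect_equal(res$energy, res2$energy, tolerance = 1e-9)

  expect_error(smoothLabels(post, g, -1), ">= 0")
})

test_that("smoothing repairs salt noise on spatially coherent labels", {
  # two coherent blobs with confident posteriors, 10% of rows flipped
  set.seed(17)
  nb <- 150
  xyz <- rbind(matrix(runif(3 * nb, 0, 0.01), ncol = 3),
               matrix(runif(3 * nb, 0.03, 0.04), ncol = 3))
  yTrue <- rep(c(1L, 0L), each = nb)
  p1 <- ifelse(yTrue == 1, 0.9, 0.1) + rnorm(2 * nb, 0, 0.03)
  p1 <- pmin(pmax(p1, 0.01), 0.99)
  flip <- sample(2 * nb, round(0.1 * 2 * nb))
  p1[flip] <- 1 - p1[flip]
  post <- cbind(1 - p1, p1)
  g <- buildNeighborGraph(xyz, 0.003)
  init <- assignLabels(post)
  sm <- smoothLabels(post, g, 0.5)
  prec <- function(lab) sum(lab == 1 & yTrue == 1) / max(sum(lab == 1), 1)
  rec <- function(lab) sum(lab == 1 & yTrue == 1) / sum(yTrue == 1)
  expect_gt(rec(sm$labels), rec(init))
  expect_gt(prec(sm$labels), prec(init))
})
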