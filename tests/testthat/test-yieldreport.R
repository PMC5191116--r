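fakeBerries <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    x = runif(n, 0, 0.05), y = runif(n, 0, 0.05), z = runif(n, 0, 0.05),
    r = runif(n, 0.005, 0.007)
  ) |> transform(diameter = 2 * r, support = sample(50:300, n, TRUE))
}

test_that("components below the minimum berry count are rejected from the yield", {
  comps <- list(list(indices = 1:500), list(indices = 501:900),
                list(indices = 901:1400))
  bpc <- list(fakeBerries(5, 1), fakeBerries(2, 2), fakeBerries(7, 3))
  rep <- finalizeYield(comps, bpc, minBerries = 3)
  expect_equal(rep@bunchCount, 2L)
  expect_equal(rep@berryCount, 12L)
  expect_equal(length(rep@diameters), 12)
  expect_equal(rep@diameterMean, mean(c(bpc[[1]]$diameter, bpc[[3]]$diameter)))
  expect_identical(rep@retained, c(TRUE, FALSE, TRUE))

  empty <- finalizeYield(list(), list(), minBerries = 3)
  expect_equal(empty@bunchCount, 0L)
  expect_equal(empty@berryCount, 0L)
  expect_equal(length(empty@diameters), 0)
})

test_that("bunch scoring implements the fusion and split counting rules", {
  # five perfect matches
  refs <- split(1:500, rep(1:5, each = 100))
  comps <- lapply(refs, function(ix) list(indices = ix))
  ev <- scoreBunches(comps, refs)
  expect_equal(ev@recall, 1)
  expect_equal(ev@precision, 1)

  # one component fusing 5 true bunches: 1 TP, 4 FN
  fused <- list(list(indices = 1:500))
  ev2 <- scoreBunches(fused, refs)
  expect_equal(ev2@tp, 1L)
  expect_equal(ev2@fn, 4L)
  expect_equal(ev2@fp, 0L)

  # one true bunch split into two components: 1 TP, 1 FP
  ev3 <- scoreBunches(list(list(indices = 1:50), list(indices = 51:100)),
                      list(1:100))
  expect_equal(ev3@tp, 1L)
  expect_equal(ev3@fp, 1L)
  expect_equal(ev3@fn, 0L)

  # reference as a per-point id vector
  ids <- rep(c(1L, 2L, NA), c(100, 100, 50))
  ev4 <- scoreBunches(list(list(indices = 1:100)), ids)
  expect_equal(ev4@tp, 1L)
  expect_equal(ev4@fn, 1L)
})

test_that("berry scoring uses an optimal capped assignment", {
  b <- fakeBerries(8, seed = 4)
  ev <- scoreBerries(b, b, matchDist = 0.001)
  expect_equal(ev@recall, 1)
  expect_equal(ev@precision, 1)
  expect_equal(ev@rmse, 0)

  spurious <- rbind(b, transform(fakeBerries(1, 5), x = 1))
  ev2 <- scoreBerries(spurious, b, matchDist = 0.001)
  expect_equal(ev2@precision, 8 / 9)
  expect_equal(ev2@recall, 1)

  # optimality against exhaustive assignment on small noisy instances
  set.seed(6)
  for (t in 1:10) {
    nR <- sample(3:5, 1)
    ref <- fakeBerries(nR)
    prd <- ref
    prd[, 1:3] <- prd[, 1:3] + matrix(rnorm(3 * nR, 0, 4e-4), ncol = 3)
    D <- as.matrix(dist(rbind(as.matrix(prd[, 1:3]), as.matrix(ref[, 1:3]))))
    D <- D[seq_len(nR), nR + seq_len(nR), drop = FALSE]
    bf <- bruteAssignment(D)
    ev3 <- scoreBerries(prd, ref, matchDist = 0.01)
    # the capped-optimal matching must reach the same TP count as the
    # exhaustive solution (all pairs are within the cap here)
    expect_equal(ev3@tp, nR)
  }
})

test_that("diameter RMSE recovers injected jitter and is symmetric", {
  rmses <- vapply(1:50, function(s) {
    ref <- fakeBerries(30, seed = 600 + s)
    prd <- transform(ref, diameter = diameter + rnorm(30, 0, 3e-4))
    scoreBerries(prd, ref, matchDist = 0.001)@rmse
  }, 1.0)
  expect_true(abs(mean(rmses) - 3e-4) < 1e-4)

  ref <- fakeBerries(20, seed = 7)
  prd <- transform(ref, diameter = diameter + rnorm(20, 0, 3e-4))
  a <- scoreBerries(prd, ref, matchDist = 0.001)@rmse
  bb <- scoreBerries(ref, prd, matchDist = 0.001)@rmse
  expect_equal(a, bb)
  perm <- sample(20)
  c2 <- scoreBerries(prd[perm, ], ref, matchDist = 0.001)@rmse
  expect_equal(a, c2)
})

test_that("degenerate scores are flagged rather than NaN", {
  ev <- scoreBerries(fakeBerries(0), fakeBerries(3, 8))
  expect_equal(ev@recall, 0)
  expect_equal(ev@precision, 0)
  expect_true(ev@degenerate)
  expect_true(ev@tp + ev@fn == 3)
})

test_that("the assignment solver is optimal on random rectangular instances", {
  set.seed(9)
  for (t in 1:25) {
    n <- sample(2:5, 1)
    m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m), n, m)
    asg <- vinecloud:::.hungarian(cost)
    expect_equal(sum(cost[cbind(seq_len(n), asg)]),
                 bruteAssignment(cost)$cost, tolerance = 1e-12)
  }
})
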