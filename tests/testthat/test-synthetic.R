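test_that("bunch packing respects the center-distance bounds and surface ownership", {
  set.seed(27)
  b <- generateBunch(12, packingGap = 0.0015, overlap = 0.0015)
  ctr <- as.matrix(b$berries[, c("x", "y", "z")])
  D <- as.matrix(dist(ctr))
  sumR <- outer(b$berries$r, b$berries$r, `+`)
  off <- upper.tri(D)
  # no pair closer than r_i + r_j - overlap
  expect_true(all(D[off] >= sumR[off] - 0.0015 - 1e-12))
  # every berry touches some other berry within the packing gap
  near <- D <= sumR + 0.0015
  diag(near) <- FALSE
  expect_true(all(rowSums(near) >= 1))

  # each sampled point lies on its owner's sphere and inside no other berry
  dOwn <- sqrt(rowSums((b$points - ctr[b$owner, ])^2))
  expect_lt(max(abs(dOwn - b$berries$r[b$owner])), 1e-9)
  for (j in seq_len(nrow(ctr))) {
    dj <- sqrt(rowSums(sweep(b$points, 2, ctr[j, ])^2))
    expect_true(all(dj >= b$berries$r[j] - 0.001 * 0.3 - 1e-12))
  }

  one <- generateBunch(1, seed = 1)
  expect_equal(nrow(one$berries), 1)
  expect_true(all(one$owner == 1))
})

test_that("scenes are deterministic given a seed", {
  cfg <- sceneConfig(rowLength = 0.4, nBunches = 1, leafCount = 3,
                     stemCount = 1, seed = 28)
  s1 <- generateScene(cfg)
  s2 <- generateScene(cfg)
  expect_identical(coords(sceneCloud(s1)), coords(sceneCloud(s2)))
  expect_identical(pointColors(sceneCloud(s1)), pointColors(sceneCloud(s2)))
  expect_identical(sceneTruth(s1), sceneTruth(s2))
  s3 <- generateScene(sceneConfig(rowLength = 0.4, nBunches = 1,
                                  leafCount = 3, stemCount = 1, seed = 29))
  expect_false(identical(coords(sceneCloud(s1)), coords(sceneCloud(s3))))
})

test_that("a noise-free scene lies exactly on its generative primitives", {
  sc <- generateScene(sceneConfig(rowLength = 0.4, nBunches = 1,
                                  leafCount = 3, stemCount = 1,
                                  noiseSigma = 0, outlierFraction = 0,
                                  backgroundFraction = 0, seed = 30))
  tr <- sceneTruth(sc)
  expect_true(all(tr$class %in% c("bunch", "canopy")))
  xyz <- coords(sceneCloud(sc))
  bunchPts <- which(tr$class == "bunch")
  tb <- sceneBerries(sc)
  d <- sqrt(rowSums((xyz[bunchPts, ] -
                       as.matrix(tb[tr$berryId[bunchPts],
                                    c("x", "y", "z")]))^2))
  expect_lt(max(abs(d - tb$r[tr$berryId[bunchPts]])), 1e-9)
})

test_that("class fractions follow the configuration", {
  fr <- vapply(1:5, function(s) {
    sc <- generateScene(sceneConfig(rowLength = 0.4, nBunches = 1,
                                    leafCount = 4, stemCount = 1,
                                    backgroundFraction = 0.05,
                                    outlierFraction = 0.01, seed = 50 + s))
    tab <- table(sceneTruth(sc)$class)
    surf <- sum(tab[c("bunch", "canopy")])
    c(tab["background"] / surf, tab["outlier"] / surf)
  }, numeric(2))
  expect_true(all(abs(fr[1, ] - 0.05) < 0.02 * 0.05 + 2e-3))
  expect_true(all(abs(fr[2, ] - 0.01) < 0.02 * 0.01 + 2e-3))
})

test_that("scene colors separate background below the brightness threshold", {
  sc <- generateScene(sceneConfig(rowLength = 0.4, nBunches = 1,
                                  leafCount = 4, stemCount = 1, seed = 31))
  v <- rgbToHsv(pointColors(sceneCloud(sc)))[, "v"]
  cl <- sceneTruth(sc)$class
  expect_true(all(v[cl == "background"] < 0.08))
  expect_true(all(v[cl %in% c("bunch", "canopy")] >= 0.10))
})

test_that("the artificial reference bunch matches its requested geometry", {
  sc <- generateArtificialBunch(nBerries = 20, seed = 32)
  tb <- sceneBerries(sc)
  expect_equal(nrow(tb), 20)
  expect_true(all(2 * tb$r >= 0.015 & 2 * tb$r <= 0.020))

  # noiseless sampling: sphere fit on each berry's own points is exact
  sc0 <- generateArtificialBunch(nBerries = 5, noiseSigma = 0, spacing = 1e-3,
                                 seed = 33)
  xyz <- coords(sceneCloud(sc0))
  tb0 <- sceneBerries(sc0)
  for (i in seq_len(5)) {
    own <- which(sceneTruth(sc0)$berryId == i)
    f <- fitSphere(xyz[own, , drop = FALSE])
    expect_lt(abs(f$radius - tb0$r[i]), 1e-9)
    expect_lt(max(abs(f$center - as.numeric(tb0[i, c("x", "y", "z")]))), 1e-8)
  }

  # rear-hemisphere culling removes the far side
  scC <- generateArtificialBunch(nBerries = 10, cull = TRUE, spacing = 1e-3,
                                 seed = 34)
  scF <- generateArtificialBunch(nBerries = 10, cull = FALSE, spacing = 1e-3,
                                 seed = 34)
  expect_lt(nPoints(sceneCloud(scC)), 0.8 * nPoints(sceneCloud(scF)))
})

test_that("infeasible packings fail loudly", {
  expect_error(
    generateBunch(80, radiusMean = 0.006, radiusSd = 0,
                  packingGap = 1e-5, overlap = 0, seed = 35),
    "packing"
  )
})
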