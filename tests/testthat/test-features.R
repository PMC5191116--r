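camAbove <- cameraTrack(matrix(c(0.01, 0.01, 1), 1))

test_that("normals of a plane point to the camera side, degenerate clouds are flagged", {
  pl <- pointCloud(planeFixture(0.02, 1e-3))
  cl <- estimateNormals(pl, 0.003, camAbove)
  nr <- pointNormals(cl)
  expect_true(all(abs(nr[, 3] - 1) < 1e-9))

  two <- estimateNormals(pointCloud(matrix(rnorm(6), 2, 3)), 0.003, camAbove)
  expect_true(all(is.na(pointNormals(two))))
  expect_error(estimateNormals(pl, -1, camAbove), "> 0")
})

test_that("sphere normals are radial within 5 degrees", {
  sph <- sphereFixture(center = c(0, 0, 0.5), r = 0.006, n = 2000)
  cl <- estimateNormals(pointCloud(sph), 0.003,
                        cameraTrack(matrix(c(0, 0, 5), 1)))
  nr <- pointNormals(cl)
  radial <- sweep(sph, 2, c(0, 0, 0.5))
  radial <- radial / sqrt(rowSums(radial^2))
  # camera far above: outward orientation only guaranteed on the upper half
  up <- radial[, 3] > 0.2
  ang <- acos(pmin(pmax(rowSums(nr[up, ] * radial[up, ]), -1), 1)) * 180 / pi
  expect_lt(max(ang), 5)
})

test_that("SFH matches an independent R implementation of the pair features", {
  set.seed(7)
  xyz <- matrix(runif(120, 0, 0.012), ncol = 3)
  cl <- estimateNormals(pointCloud(xyz), 0.005,
                        cameraTrack(matrix(c(0, 0, 1), 1)))
  sfh <- computeSFH(cl, 0.009)
  nr <- pointNormals(cl)
  for (i in c(1, 10, 25)) {
    expect_equal(unclass(sfh)[i, ], bruteSfhPoint(xyz, nr, i, 0.009),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("SFH is a probability vector, concentrated for planes, invariant to rigid motion", {
  pl <- planeFixture(0.02, 1e-3)
  cl <- estimateNormals(pointCloud(pl), 0.003, camAbove)
  sfh <- unclass(computeSFH(cl, 0.009))
  expect_true(all(abs(rowSums(sfh) - 1) < 1e-9))
  # parallel normals: f1 = 0 (center bin), f3 = 0 (center bin); mass sits in
  # the 5 bins these two coordinates pin down
  pinned <- as.vector(outer(2 * 25 + 0:4 * 5, 2, `+`)) + 1
  expect_gt(min(rowSums(sfh[, pinned, drop = FALSE])), 0.999)

  set.seed(8)
  sph <- sphereFixture(r = 0.006, n = 800)
  cams <- cameraTrack(matrix(c(0, -0.5, 0), 1))
  s1 <- unclass(computeSFH(estimateNormals(pointCloud(sph), 0.003, cams), 0.009))
  R <- randomRotation3()
  tr <- c(1, -2, 0.5)
  sph2 <- sweep(sph %*% t(R), 2, tr, `+`)
  cams2 <- cameraTrack(sweep(cameraPositions(cams) %*% t(R), 2, tr, `+`))
  s2 <- unclass(computeSFH(estimateNormals(pointCloud(sph2), 0.003, cams2), 0.009))
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("sphere and plane patches have separable mean histograms", {
  set.seed(9)
  cams <- cameraTrack(matrix(c(0, 0, 1), 1))
  histFor <- function(xyz) {
    cl <- estimateNormals(pointCloud(xyz), 0.003, cams)
    sfh <- computeSFH(cl, 0.009)
    colMeans(unclass(sfh)[attr(sfh, "valid"), , drop = FALSE])
  }
  nPatch <- 30
  sphH <- planH <- matrix(0, nPatch, 125)
  for (i in seq_len(nPatch)) {
    sph <- sphereFixture(r = 0.006, n = 400)
    sph <- sph + matrix(rnorm(length(sph), 0, 1e-4), ncol = 3)
    sphH[i, ] <- histFor(sph[sph[, 3] > 0, ])   # upper hemisphere patch
    pl <- planeFixture(0.015, 1e-3)
    pl[, 3] <- rnorm(nrow(pl), 0, 1e-4)
    planH[i, ] <- histFor(pl)
  }
  mSph <- colMeans(sphH)
  mPlan <- colMeans(planH)
  between <- sum(abs(mSph - mPlan))
  withinSph <- mean(apply(sphH, 1, function(h) sum(abs(h - mSph))))
  withinPlan <- mean(apply(planH, 1, function(h) sum(abs(h - mPlan))))
  expect_gt(between, withinSph)
  expect_gt(between, withinPlan)
  # nearest-centroid classification of the patches
  lab <- apply(rbind(sphH, planH), 1, function(h) {
    sum(abs(h - mSph)) < sum(abs(h - mPlan))
  })
  acc <- mean(lab == rep(c(TRUE, FALSE), each = nPatch))
  expect_gte(acc, 0.95)
})

test_that("computeFeatures concatenates SFH and scaled HSV with validity", {
  set.seed(10)
  xyz <- matrix(runif(60, 0, 0.01), ncol = 3)
  cols <- matrix(runif(60), ncol = 3)
  cl <- estimateNormals(pointCloud(xyz, colors = cols), 0.004, camAbove)
  sfh <- computeSFH(cl, 0.009)
  feat <- computeFeatures(cl, sfh)
  expect_equal(dim(feat), c(20, 128))
  v <- attr(feat, "valid")
  expect_true(all(abs(rowSums(feat[v, 1:125, drop = FALSE]) - 1) < 1e-9))
  hsv <- rgbToHsv(cols)
  expect_equal(feat[, 126], hsv[, 1] / 360, ignore_attr = TRUE)
  expect_equal(feat[, 127:128], hsv[, 2:3], ignore_attr = TRUE)
  expect_error(computeFeatures(cl, unclass(sfh)[, 1:10]), "125")

  one <- estimateNormals(
    pointCloud(matrix(0, 1, 3), colors = matrix(0.5, 1, 3)), 0.003, camAbove
  )
  f1 <- computeFeatures(one, computeSFH(one, 0.009))
  expect_equal(dim(f1), c(1, 128))
  expect_false(attr(f1, "valid"))
})
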