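test_that("rgbToHsv matches the hexcone formulas and grDevices", {
  expect_equal(rgbToHsv(matrix(c(1, 0, 0), 1))[1, ], c(0, 1, 1),
               ignore_attr = TRUE)
  expect_equal(rgbToHsv(matrix(c(0.5, 0.5, 0.5), 1))[1, ], c(0, 0, 0.5),
               ignore_attr = TRUE)
  expect_equal(rgbToHsv(matrix(c(0.2, 0.4, 0.6), 1))[1, ],
               scalarRgbToHsv(0.2, 0.4, 0.6), ignore_attr = TRUE)
  set.seed(1)
  cols <- matrix(runif(300), ncol = 3)
  mine <- rgbToHsv(cols)
  ref <- t(grDevices::rgb2hsv(t(cols), maxColorValue = 1))
  expect_equal(mine[, 1], ref[, 1] * 360, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(mine[, 2:3], ref[, 2:3], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(rgbToHsv(matrix(c(1.2, 0, 0), 1)), "\\[0, 1\\]")
  # inverse
  expect_equal(hsvToRgb(mine), cols, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("background removal keeps exactly the points above the V threshold", {
  dark <- pointCloud(matrix(rnorm(30), ncol = 3),
                     colors = matrix(0.05, 10, 3))
  expect_equal(nPoints(removeBackground(dark, 0.1)$cloud), 0)
  expect_equal(length(removeBackground(dark, 0)$removed), 0)
  expect_error(removeBackground(pointCloud(matrix(0, 2, 3)), 0.1), "colors")

  sc <- generateScene(sceneConfig(rowLength = 0.4, nBunches = 1,
                                  leafCount = 4, stemCount = 1, seed = 5))
  res <- removeBackground(sceneCloud(sc), 0.10)
  bg <- which(sceneTruth(sc)$class == "background")
  expect_setequal(res$removed, bg)
})

test_that("SOR removal set matches the brute-force kNN oracle", {
  # regular grid with one displaced point
  g <- seq(0, 0.01, by = 0.001)
  grid <- as.matrix(expand.grid(g, g, 0))
  grid[40, ] <- grid[40, ] + c(0.05, 0.05, 0)
  res <- sorFilter(pointCloud(grid), k = 6, sigmaMult = 1)
  expect_identical(res$removed, 40L)

  set.seed(2)
  cloud <- pointCloud(matrix(runif(600, 0, 0.05), ncol = 3))
  res2 <- sorFilter(cloud, k = 6, sigmaMult = 1)
  d <- bruteMeanKnnDist(coords(cloud), 6)
  expect_equal(res2$meanDist, d, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(res2$removed, which(d > mean(d) + stats::sd(d)))

  expect_equal(length(sorFilter(cloud, 6, Inf)$removed), 0)
  expect_error(sorFilter(pointCloud(matrix(0, 3, 3)), k = 6), "more points")
})

test_that("MLS leaves plane and quadratic surfaces fixed and denoises a sphere", {
  pl <- planeFixture(0.02, 5e-4)
  sm <- mlsSmooth(pointCloud(pl), 0.004, 2)
  expect_lt(max(abs(coords(sm) - pl)), 1e-9)

  # quadratic height field, order 2
  g <- seq(-0.01, 0.01, 5e-4)
  uv <- as.matrix(expand.grid(g, g))
  quad <- cbind(uv, 0.5 * uv[, 1]^2 + 0.8 * uv[, 1] * uv[, 2] - 0.3 * uv[, 2]^2)
  sm2 <- mlsSmooth(pointCloud(quad), 0.004, 2)
  expect_lt(max(abs(coords(sm2) - quad)), 1e-6)

  set.seed(3)
  sph <- sphereFixture(r = 0.006, n = 2500)
  noisy <- sph + (sph / 0.006) * stats::rnorm(nrow(sph), 0, 2e-4)
  sm3 <- mlsSmooth(pointCloud(noisy), 0.004, 2)
  rmsRad <- function(x) sqrt(mean((sqrt(rowSums(x^2)) - 0.006)^2))
  expect_lt(rmsRad(coords(sm3)), rmsRad(noisy))

  expect_error(mlsSmooth(pointCloud(pl), -1), "> 0")
  # attributes and point count carried through
  pc <- pointCloud(pl, colors = matrix(0.5, nrow(pl), 3))
  smc <- mlsSmooth(pc, 0.004, 2)
  expect_equal(nPoints(smc), nrow(pl))
  expect_equal(pointColors(smc), pointColors(pc))
})

test_that("minimum-distance subsampling keeps the earlier point and satisfies d_min", {
  two <- pointCloud(matrix(c(0, 0, 0, 5e-4, 0, 0), 2, 3, byrow = TRUE))
  res <- subsampleMinDist(two, 0.001)
  expect_identical(res$kept, 1L)

  spaced <- pointCloud(cbind(seq(0, 0.01, 0.002), 0, 0))
  expect_equal(subsampleMinDist(spaced, 0.001)$kept, 1:6)

  set.seed(4)
  cloud <- pointCloud(matrix(runif(3e4, 0, 0.1), ncol = 3))
  res2 <- subsampleMinDist(cloud, 0.004)
  d <- as.matrix(dist(coords(res2$cloud)))
  diag(d) <- Inf
  expect_gte(min(d), 0.004)
  # maximality: every dropped point is within d_min of some kept point
  dropped <- setdiff(seq_len(nPoints(cloud)), res2$kept)
  dd <- as.matrix(dist(coords(cloud)))[dropped, res2$kept, drop = FALSE]
  expect_true(all(apply(dd, 1, min) < 0.004))
})

test_that("the preprocessing chain runs in order and never creates points", {
  sc <- generateScene(sceneConfig(rowLength = 0.4, nBunches = 1,
                                  leafCount = 4, stemCount = 1, seed = 6))
  prep <- preprocessCloud(sceneCloud(sc), pipelineConfig())
  expect_true(all(diff(prep$counts) <= 0))
  expect_equal(nPoints(prep$cloud), unname(prep$counts["subsample"]))
  expect_equal(length(prep$kept), nPoints(prep$cloud))
  # kept indices refer to the original cloud
  expect_true(all(prep$kept >= 1 & prep$kept <= nPoints(sceneCloud(sc))))
})
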