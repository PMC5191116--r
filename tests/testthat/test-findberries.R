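test_that("sphere fitting recovers exact spheres and rejects degenerate input", {
  pts <- sphereFixture(center = c(1, 2, 3), r = 0.006, n = 20)
  f <- fitSphere(pts)
  expect_equal(f$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(f$radius, 0.006, tolerance = 1e-9)
  expect_lt(f$rms, 1e-9)

  expect_error(fitSphere(planeFixture(0.01, 2e-3)), "coplanar")
  expect_error(fitSphere(matrix(rnorm(9), 3, 3)), "at least 4")
})

test_that("hemisphere fits stay within 0.5 mm of the true radius under noise", {
  errs <- vapply(1:100, function(s) {
    set.seed(400 + s)
    pts <- sphereFixture(r = 0.006, n = 400)
    pts <- pts[pts[, 3] > 0, ]
    pts <- pts + (pts / 0.006) * rnorm(nrow(pts), 0, 2e-4)
    abs(fitSphere(pts)$radius - 0.006)
  }, 1.0)
  expect_lt(max(errs), 5e-4)
})

test_that("the four-stage candidate hierarchy reports the first failing check", {
  cfg <- pipelineConfig()
  cams <- cameraTrack(matrix(c(0, -0.6, 0), 1))
  sph <- sphereFixture(r = 0.006, n = 600)

  # stage 1: radius out of range
  v <- evaluateBerryCandidate(list(center = c(0, 0, 0), radius = 0.015),
                              sph, cams, cfg)
  expect_identical(v$verdict, "reject")
  expect_identical(v$reason, "radius")

  # full sphere facing the camera: accepted
  v2 <- evaluateBerryCandidate(list(center = c(0, 0, 0), radius = 0.006),
                               sph, cams, cfg)
  expect_identical(v2$verdict, "accept")
  expect_gte(v2$nLine, cfg$minLinePoints)

  # rear half only (nothing between center and camera): valley rejection
  rear <- sph[sph[, 2] > 0, ]
  v3 <- evaluateBerryCandidate(list(center = c(0, 0, 0), radius = 0.006),
                               rear, cams, cfg)
  expect_identical(v3$verdict, "reject")
  expect_identical(v3$reason, "valley")

  # stage 2: a diffuse ball has no coherent shell
  set.seed(22)
  ball <- matrix(runif(1500, -0.006, 0.006), ncol = 3)
  v4 <- evaluateBerryCandidate(list(center = c(0, 0, 0), radius = 0.006),
                               ball, cams, cfg)
  expect_identical(v4$verdict, "reject")
  expect_identical(v4$reason, "support")
})

test_that("overlap contests keep the better-supported sphere", {
  cfg <- pipelineConfig()
  cams <- cameraTrack(matrix(c(0, -0.6, 0), 1))
  sph <- sphereFixture(r = 0.006, n = 600)
  # an accepted berry displaced 2 mm from the truth, with weak support
  weak <- data.frame(x = 0.002, y = 0, z = 0, r = 0.006, support = 50)
  v <- evaluateBerryCandidate(list(center = c(0, 0, 0), radius = 0.006),
                              sph, cams, cfg, accepted = weak)
  expect_identical(v$verdict, "accept")
  expect_identical(v$evict, 1L)
  # same contest against a stronger incumbent: candidate rejected
  strong <- transform(weak, support = 10000)
  v2 <- evaluateBerryCandidate(list(center = c(0, 0, 0), radius = 0.006),
                               sph, cams, cfg, accepted = strong)
  expect_identical(v2$verdict, "reject")
  expect_identical(v2$reason, "overlap")
})

test_that("findBerries recovers a clean berry exactly and ignores a plane", {
  sc <- generateArtificialBunch(nBerries = 1, diameterRange = c(0.012, 0.012),
                                noiseSigma = 0, spacing = 5e-4, seed = 23)
  b <- findBerries(coords(sceneCloud(sc)), sceneCameras(sc),
                   pipelineConfig(), seed = 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$r, 0.006, tolerance = 1e-4 / 6)

  leaf <- planeFixture(0.05, 1e-3)
  b2 <- findBerries(leaf, cameraTrack(matrix(c(0.02, 0.02, 0.6), 1)),
                    pipelineConfig(), seed = 2)
  expect_equal(nrow(b2), 0)
})

test_that("a generated 10-berry bunch is recovered with matched centers", {
  sc <- generateArtificialBunch(nBerries = 10, diameterRange = c(0.011, 0.013),
                                noiseSigma = 2e-4, spacing = 1e-3, seed = 24)
  xyz <- coords(sceneCloud(sc))
  cfg <- pipelineConfig()
  tb <- sceneBerries(sc)
  # a tightly packed bunch can bury a berry's camera-facing crown inside a
  # neighbor; such berries are valley-rejected by contract, so the
  # recoverable reference is the set whose true sphere passes the hierarchy
  okTrue <- vapply(seq_len(nrow(tb)), function(i) {
    v <- evaluateBerryCandidate(
      list(center = as.numeric(tb[i, c("x", "y", "z")]), radius = tb$r[i]),
      xyz, sceneCameras(sc), cfg
    )
    identical(v$verdict, "accept")
  }, TRUE)
  expect_gte(sum(okTrue), 8)
  counts <- integer(10)
  for (s in 1:10) {
    b <- findBerries(xyz, sceneCameras(sc), cfg, seed = 30 + s)
    counts[s] <- nrow(b)
    ev <- scoreBerries(b, tb, matchDist = 0.002)
    expect_equal(ev@fp, 0)  # every detection matches a true berry
  }
  expect_true(all(abs(counts - sum(okTrue)) <= 1))
})

test_that("accepted berries have disjoint support and re-pass all four checks", {
  sc <- generateArtificialBunch(nBerries = 8, diameterRange = c(0.011, 0.013),
                                noiseSigma = 2e-4, spacing = 1e-3, seed = 25)
  xyz <- coords(sceneCloud(sc))
  cfg <- pipelineConfig()
  b <- findBerries(xyz, sceneCameras(sc), cfg, seed = 3)
  sup <- attr(b, "supportIndices")
  expect_equal(anyDuplicated(unlist(sup)), 0)
  expect_true(all(b$r >= cfg$rMin & b$r <= cfg$rMax))
  expect_equal(b$diameter, 2 * b$r)
  expect_true(all(diff(b$support) <= 0))  # sorted by support
  for (i in seq_len(nrow(b))) {
    others <- b[-i, , drop = FALSE]
    v <- evaluateBerryCandidate(
      list(center = as.numeric(b[i, c("x", "y", "z")]), radius = b$r[i]),
      xyz, sceneCameras(sc), cfg,
      accepted = transform(others, support = others$support)
    )
    # radius, support and valley checks must re-pass; the overlap check is
    # against the deliberately conservative full-cloud support counts
    expect_false(identical(v$reason, "radius"))
    expect_false(identical(v$reason, "support"))
    expect_false(identical(v$reason, "valley"))
  }
})

test_that("findBerries is deterministic given a seed", {
  sc <- generateArtificialBunch(nBerries = 6, diameterRange = c(0.011, 0.013),
                                noiseSigma = 2e-4, spacing = 1e-3, seed = 26)
  xyz <- coords(sceneCloud(sc))
  b1 <- findBerries(xyz, sceneCameras(sc), pipelineConfig(), seed = 7)
  b2 <- findBerries(xyz, sceneCameras(sc), pipelineConfig(), seed = 7)
  expect_identical(b1, b2)
})
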