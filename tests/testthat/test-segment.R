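blob <- function(center, n, sd = 0.002, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sweep(matrix(rnorm(3 * n, 0, sd), ncol = 3), 2, center, `+`)
}

test_that("connected components at a distance threshold behave as single linkage", {
  two <- rbind(blob(c(0, 0, 0), 100, seed = 18), blob(c(0.05, 0, 0), 100))
  expect_equal(length(unique(connectedComponents(two, 0.005))), 2)

  chain <- cbind(seq(0, 0.04, by = 0.004), 0, 0)
  expect_equal(length(unique(connectedComponents(chain, 0.005))), 1)

  set.seed(19)
  for (t in 1:10) {
    xyz <- matrix(runif(900, 0, 0.05), ncol = 3)
    d <- runif(1, 0.003, 0.01)
    expect_true(samePartition(connectedComponents(xyz, d),
                              bruteComponents(xyz, d)))
  }
})

test_that("component count is monotone in the distance threshold", {
  set.seed(20)
  xyz <- matrix(runif(600, 0, 0.04), ncol = 3)
  counts <- vapply(c(0.01, 0.008, 0.006, 0.004, 0.002), function(d) {
    length(unique(connectedComponents(xyz, d)))
  }, 1.0)
  expect_true(all(diff(counts) >= 0))
})

test_that("size filtering deletes exactly the undersized components", {
  comps <- list(list(indices = 1:10, stage = "first"),
                list(indices = 11:510, stage = "first"))
  flt <- filterSmall(comps, 400)
  expect_equal(length(flt$components), 1)
  expect_equal(flt$components[[1]]$indices, 11:510)
  expect_equal(length(flt$deleted), 1)
  expect_equal(length(filterSmall(comps, 1)$components), 2)
})

test_that("oversized components are split at the tighter threshold and re-filtered", {
  # two dense slabs separated by a 3 mm gap: fused at 5 mm, split at 1 mm
  g <- expand.grid(x = seq(0, 0.02, 5e-4), y = seq(0, 0.01, 5e-4))
  slab1 <- cbind(g$x, g$y, 0)
  slab2 <- cbind(g$x, g$y, 0.003)
  xyz <- rbind(slab1, slab2)
  ids <- connectedComponents(xyz, 0.005)
  expect_equal(length(unique(ids)), 1)
  comps <- list(list(indices = seq_len(nrow(xyz)), stage = "first"))
  spl <- splitLarge(comps, xyz, maxPoints = 1000, ccDist2 = 0.001,
                    minPoints = 100)
  expect_equal(length(spl$components), 2)
  # the split partitions the parent exactly
  expect_setequal(unlist(lapply(spl$components, `[[`, "indices")),
                  seq_len(nrow(xyz)))
  expect_true(all(vapply(spl$components, function(cp) cp$stage, "") == "split"))

  # a component at or below maxPoints is untouched
  spl2 <- splitLarge(comps, xyz, maxPoints = nrow(xyz), ccDist2 = 0.001)
  expect_identical(spl2$components, comps)
})

test_that("segmentBunches produces one component per well-separated bunch", {
  sc <- generateScene(sceneConfig(rowLength = 0.8, nBunches = 3,
                                  leafCount = 6, stemCount = 1, seed = 21))
  cl <- sceneCloud(sc)
  pointLabels(cl) <- as.integer(sceneTruth(sc)$class == "bunch")
  seg <- segmentBunches(cl, pipelineConfig())
  expect_equal(length(seg$components), 3)
  # components are disjoint subsets of bunch-labeled points
  all <- unlist(lapply(seg$components, `[[`, "indices"))
  expect_equal(anyDuplicated(all), 0)
  expect_true(all(pointLabels(cl)[all] == 1L))
})
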