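test_that("analytic shape truths are self-consistent (6V/DS identity)", {
  set.seed(11)
  shapes <- list()
  for (i in 1:20) {
    shapes <- c(shapes,
      list(sphereShape(c(5, 5, 5), runif(1, 0.3, 3)),
           ellipsoidShape(c(5, 5, 5), runif(3, 0.3, 3)),
           capsuleShape(c(5, 5, 5), radius = runif(1, 0.2, 1),
                        length = runif(1, 0, 4))))
  }
  for (s in shapes)
    expect_equal(6 * s$trueVolume / (s$trueDiameter * s$trueSurface),
                 s$trueInvSphericity, tolerance = 1e-9)
  # closed forms at reference values
  s <- sphereShape(c(15, 15, 15), 10)
  expect_equal(s$trueVolume, 4188.7902, tolerance = 1e-6)
  expect_equal(s$trueInvSphericity, 1)
})

test_that("stack generation is seeded-deterministic and rejects out-of-bounds shapes", {
  spec <- cleanStackSpec(list(sphereShape(c(3, 4, 4), 1.2)),
                         shapeZyx = c(16, 32, 32))
  a <- generateStack(spec, seed = 7)
  b <- generateStack(spec, seed = 7)
  expect_identical(voxelData(a$stack), voxelData(b$stack))
  expect_error(
    stackSpec(shapeZyx = c(10, 10, 10), voxelSizeZyx = c(1, 1, 1),
              shapes = list(sphereShape(c(5, 5, 9), 3))),
    "outside the stack bounds")
})

test_that("noise-free stacks give exact foreground recovery of separated shapes", {
  shapes <- list(ellipsoidShape(c(3, 3, 3), c(1, 1.5, 1)),
                 ellipsoidShape(c(3, 8, 5), c(1, 1, 2)),
                 ellipsoidShape(c(3, 4, 8), c(1.2, 1, 1)))
  g <- generateStack(cleanStackSpec(shapes), seed = 1)
  objs <- segmentObjects(g$stack, "mito_green", threshold = 50)
  expect_length(objs, 3)
  # union of object voxels equals foreground mask (conservation)
  ch <- voxelData(g$stack, "mito_green")
  expect_equal(sum(vapply(objs, nVoxels, integer(1))), sum(ch > 50))
})

test_that("cohort generator applies effects to the right groups only", {
  spec <- cohortSpec(groups = c("control", "hom"), nClustersPerGroup = 3,
                     effects = list(hom = list(aspect = 4)))
  co <- generateCohort(spec, seed = 3)
  tr <- co$truth
  expect_equal(nrow(tr), 6)
  # aspect 4:1 lowers true inverse sphericity strictly (prolate formula)
  expect_true(max(tr$trueMeanInvSphericity[tr$group == "hom"]) <
              min(tr$trueMeanInvSphericity[tr$group == "control"]))
  # null cohort: both groups generated from identical distributions
  null <- cohortSpec(groups = c("a", "b"), nClustersPerGroup = 2)
  expect_identical(mitomorph:::.groupEffect(null, "a"),
                   mitomorph:::.groupEffect(null, "b"))
  # reproducible
  co2 <- generateCohort(spec, seed = 3)
  expect_identical(co$truth, co2$truth)
  expect_error(cohortSpec(effects = list(nosuch = list(aspect = 2))),
               "unknown group label")
})

test_that("beam generator: immobile, monotone-up and seeded determinism", {
  still <- generateBeamSeries(beamSpec(durationS = 60, moveModel = "stay"),
                              seed = 1)
  expect_equal(still$truth$nClimbs, 0)
  expect_equal(still$truth$totalHeight, 0)
  up <- generateBeamSeries(beamSpec(durationS = 60,
                                    moveModel = "monotone_up"), seed = 1)
  expect_equal(up$truth$nClimbs, 1)
  expect_equal(up$truth$totalHeight, 51)  # first-to-last beam span
  s1 <- generateBeamSeries(beamSpec(durationS = 300), seed = 9)
  s2 <- generateBeamSeries(beamSpec(durationS = 300), seed = 9)
  expect_identical(beamIndices(s1$series), beamIndices(s2$series))
})

test_that("lane generator reproduces loading structure", {
  g <- generateLaneTable(laneSpec(trueLoading = c(2, 1), noiseSd = 0),
                         seed = 1)
  lnf <- laneNormalizationFactors(g$lanes$total_protein_signal)
  expect_equal(lnf, c(1.0, 0.5))
  norm <- normalizeLaneTable(g$lanes)
  # equal true biology: loading cancels exactly
  expect_equal(norm$normalized_14[1], norm$normalized_14[2])
  expect_equal(norm$normalized_12[1], norm$normalized_12[2])
  n1 <- generateLaneTable(laneSpec(trueLoading = 1:4, noiseSd = 0.1), seed = 5)
  n2 <- generateLaneTable(laneSpec(trueLoading = 1:4, noiseSd = 0.1), seed = 5)
  expect_identical(n1$lanes, n2$lanes)
})
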