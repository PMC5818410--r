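test_that("Otsu threshold separates bimodal data and matches exhaustive search", {
  x <- c(rep(10, 90), rep(200, 10))
  t0 <- autoThreshold(x)
  expect_gt(t0, 10)
  expect_lt(t0, 200)
  set.seed(21)
  for (i in 1:25) {
    x <- sample(0:255, 400, replace = TRUE,
                prob = 0.7 * dnorm(0:255, 60, 20) +
                       0.3 * dnorm(0:255, 180, 25))
    expect_equal(autoThreshold(x), otsuBrute(x))
  }
  expect_warning(t1 <- autoThreshold(rep(5, 100)), "constant")
  expect_true(is.na(t1))
})

test_that("Otsu foreground is invariant to positive intensity scaling (8-bit)", {
  set.seed(4)
  x <- sample(0:255, 500, replace = TRUE,
              prob = 0.8 * dnorm(0:255, 40, 15) + 0.2 * dnorm(0:255, 200, 20))
  t1 <- autoThreshold(x)
  t3 <- autoThreshold(3L * x)
  expect_identical(x > t1, 3L * x > t3)
})

test_that("connected components follow the 26/6 conventions and flood-fill oracle", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # shares only a corner
  expect_equal(attr(labelComponents(m, 26L), "n"), 1L)
  expect_equal(attr(labelComponents(m, 6L), "n"), 2L)
  set.seed(31)
  for (i in 1:12) {
    d <- sample(4:20, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.25, d)
    for (conn in c(6L, 26L))
      expect_equal(attr(labelComponents(m, conn), "n"),
                   floodFillCount(m, conn))
  }
})

test_that("segmented objects partition the foreground and obey the ROI centroid rule", {
  shapes <- list(sphereShape(c(3, 3, 3), 1.1),
                 sphereShape(c(3, 7.5, 7.5), 1.3))
  g <- generateStack(cleanStackSpec(shapes), seed = 2)
  objs <- segmentObjects(g$stack, "mito_green", threshold = 50)
  expect_length(objs, 2)
  ch <- voxelData(g$stack, "mito_green")
  lab <- labelComponents(ch > 50)
  expect_equal(sum(vapply(objs, nVoxels, integer(1))), sum(lab > 0))

  d <- dim(ch)
  # ROI covering only the first sphere's neighbourhood
  mask <- array(FALSE, d)
  mask[, 1:25, 1:25] <- TRUE
  roi <- new("RoiMask", mask = mask, somaLabels = array(0L, d),
             somaVolumes = numeric(0), voxelSize = voxelSize(g$stack))
  kept <- restrictToRoi(objs, roi)
  expect_length(kept, 1)
  full <- new("RoiMask", mask = array(TRUE, d), somaLabels = array(0L, d),
              somaVolumes = numeric(0), voxelSize = voxelSize(g$stack))
  expect_length(restrictToRoi(objs, full), 2)  # all inside: identity
  # straddling: ROI boundary cuts the second sphere but contains its centroid
  mask2 <- array(FALSE, d)
  mask2[, 1:32, ] <- TRUE
  roi2 <- new("RoiMask", mask = mask2, somaLabels = array(0L, d),
              somaVolumes = numeric(0), voxelSize = voxelSize(g$stack))
  expect_length(restrictToRoi(objs, roi2), 2)
})

test_that("TH ROI recovers soma count and volume", {
  shapes <- list()
  somas <- list(sphereShape(c(3.2, 3.2, 3.2), 2.2, intensity = 120,
                            channel = "th"),
                sphereShape(c(3.2, 8.6, 8.6), 2.2, intensity = 120,
                            channel = "th"))
  g <- generateStack(cleanStackSpec(shapes, shapeZyx = c(20, 50, 50),
                                    thSomas = somas), seed = 1)
  roi <- buildRoi(g$stack, minSomaVolume = 10)
  expect_equal(nCells(roi), 2L)
  trueV <- 4 / 3 * pi * 2.2^3
  expect_true(all(abs(somaVolumes(roi) - trueV) / trueV < 0.05))

  blank <- generateStack(cleanStackSpec(list(), shapeZyx = c(8, 10, 10)),
                         seed = 1)
  expect_warning(roi0 <- buildRoi(blank$stack), "empty ROI|no TH")
  expect_equal(nCells(roi0), 0L)
})

test_that("saturation fraction QC matches the generator target", {
  g <- generateStack(stackSpec(shapeZyx = c(16, 48, 48),
                               shapes = list(ellipsoidShape(c(2.5, 5.6, 5.6),
                                                            c(1.8, 4, 4))),
                               thSomas = list(ellipsoidShape(
                                 c(2.5, 5.6, 5.6), c(2.2, 5, 5),
                                 intensity = 120, channel = "th")),
                               saturationTarget = 0.02), seed = 6)
  f <- saturationFraction(g$stack, "mito_green", target = NULL)
  expect_true(abs(mean(voxelData(g$stack) >= bitMax(g$stack)) - 0.02) < 0.005)

  clean <- generateStack(cleanStackSpec(list(sphereShape(c(3, 3, 3), 1))),
                         seed = 1)
  expect_warning(f0 <- saturationFraction(clean$stack, "mito_green"),
                 "saturation")
  expect_equal(f0, 0)
  sat <- ImageStack(array(7, c(1, 2, 2, 2)), c(1, 1, 1), c(mito_green = 1L),
                    bitMax = 7)
  expect_warning(f1 <- saturationFraction(sat, "mito_green"))
  expect_equal(f1, 1)
})
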