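test_that("object volume is voxel count times voxel volume", {
  o <- makeObject(cbind(rep(1, 100), seq_len(100), rep(1, 100)),
                  voxelSize = c(0.1, 0.1, 0.34))
  expect_equal(objectVolume(o), 0.34)  # 100 voxels, z-step from the study
  expect_equal(objectVolume(makeObject(c(1, 1, 1))), 1.0)
  s <- sphereObject(10)
  expect_true(abs(objectVolume(s) - 4188.79) / 4188.79 < 0.02)
})

test_that("surface area matches analytic spheres, the scaling law and the box fallback", {
  s <- sphereObject(10)
  a <- objectSurfaceArea(s)
  expect_true(abs(a - 4 * pi * 100) / (4 * pi * 100) < 0.03)
  s2 <- sphereObject(20)
  expect_true(abs(objectSurfaceArea(s2) / a - 4) / 4 < 0.05)
  expect_equal(objectSurfaceArea(makeObject(c(1, 1, 1))), 6.0)
})

test_that("maximum diameter equals the all-pairs brute force", {
  two <- makeObject(rbind(c(1, 1, 1), c(1, 1, 6)))
  expect_equal(objectMaxDiameter(two), 5.0)
  s <- sphereObject(10)
  expect_true(abs(objectMaxDiameter(s) - 20) / 20 < 0.05)
  set.seed(12)
  for (i in 1:10) {
    co <- unique(matrix(sample(1:8, 3 * 20, replace = TRUE), ncol = 3))
    vs <- runif(3, 0.2, 1)
    o <- makeObject(co, voxelSize = vs)
    pts <- sweep(co - 1, 2, vs, `*`)
    expect_equal(objectMaxDiameter(o), feretBrute(pts))
  }
})

test_that("inverse sphericity: sphere = 1, decreasing in aspect, digitized tolerance", {
  expect_equal(inverseSphericity(4 / 3 * pi, 2, 4 * pi), 1.0)
  # closed-form ellipsoids a:1:1
  vals <- vapply(c(1, 2, 4, 8), function(a)
    ellipsoidShape(c(9, 9, 9), c(1, 1, a))$trueInvSphericity, numeric(1))
  expect_true(all(diff(vals) < 0))
  # prolate (4,1,1) against the independent closed-form surface oracle
  V <- 4 / 3 * pi * 4
  expect_equal(6 * V / (8 * prolateSurface(4, 1)), 0.3103, tolerance = 1e-3)
  expect_equal(ellipsoidShape(c(9, 9, 9), c(1, 1, 4))$trueInvSphericity,
               6 * V / (8 * prolateSurface(4, 1)), tolerance = 1e-9)
  s <- sphereObject(10)
  m <- objectMetrics(list(s))
  expect_true(abs(m$inverseSphericity - 1) <= 0.1)
  expect_error(inverseSphericity(1, 0, 1), "> 0")
})

test_that("morphometrics are scale-equivariant in voxel size", {
  set.seed(7)
  co <- unique(matrix(sample(1:6, 3 * 30, replace = TRUE), ncol = 3))
  o1 <- makeObject(co, voxelSize = c(0.3, 0.25, 0.25))
  o2 <- makeObject(co, voxelSize = 2 * c(0.3, 0.25, 0.25))
  expect_equal(objectVolume(o2), 8 * objectVolume(o1))
  expect_equal(objectSurfaceArea(o2), 4 * objectSurfaceArea(o1),
               tolerance = 1e-8)
  expect_equal(objectMaxDiameter(o2), 2 * objectMaxDiameter(o1))
  m1 <- objectMetrics(list(o1)); m2 <- objectMetrics(list(o2))
  expect_equal(m1$inverseSphericity, m2$inverseSphericity, tolerance = 1e-8)
})

test_that("size histogram follows the three-equal-bin rule", {
  h <- sizeHistogram(c(0.2, 0.5, 1.1, 2.0, 3.2))
  expect_equal(diff(h$binEdges), rep(1.0, 3))
  expect_equal(h$counts, c(3L, 1L, 1L))
  expect_equal(h$binCenters, c(0.7, 1.7, 2.7))
  # the maximum lands in the last (closed) bin, never a phantom fourth
  expect_equal(sum(h$counts), 5L)
  h1 <- sizeHistogram(2.5)
  expect_equal(h1$counts, c(1L, 0L, 0L))
  expect_true(isTRUE(attr(h1, "degenerate")))
  set.seed(3)
  for (i in 1:10) {
    v <- rlnorm(sample(2:40, 1))
    h <- sizeHistogram(v)
    expect_equal(sum(h$counts), length(v))
    expect_equal(3 * diff(h$binEdges)[1], max(v) - min(v))
  }
})

test_that("largest-fraction selection uses the ceiling rule with stable ties", {
  m <- data.frame(volume = rep(1, 100), inverseSphericity = seq_len(100))
  top <- largestFraction(m)
  expect_equal(nrow(top), 5)
  expect_equal(top$inverseSphericity, 1:5)  # ties: input order
  expect_equal(nrow(largestFraction(data.frame(volume = rnorm(10) + 10))), 1)
})

test_that("network volume per cell divides object volume by soma volume", {
  d <- c(6, 12, 12)
  lab <- array(0L, d)
  lab[2:5, 2:6, 2:6] <- 1L   # soma 1: 4*5*5 = 100 voxels
  lab[2:5, 8:11, 8:11] <- 2L # soma 2: 4*4*4 = 64 voxels
  roi <- new("RoiMask", mask = lab > 0, somaLabels = lab,
             somaVolumes = c(100, 64), voxelSize = c(1, 1, 1))
  o1 <- makeObject(rbind(c(3, 3, 3), c(3, 3, 4), c(3, 4, 3), c(3, 4, 4),
                         c(4, 3, 3)))                       # 5 um^3 in soma 1
  o2 <- makeObject(rbind(c(3, 9, 9), c(3, 9, 10)))          # 2 um^3 in soma 2
  nv <- networkVolumePerCell(list(o1, o2), roi)
  expect_equal(unname(nv), c(5 / 100, 2 / 64))
  # soma with no objects scores 0; assigned volumes partition the total
  nv1 <- networkVolumePerCell(list(o1), roi)
  expect_equal(unname(nv1), c(0.05, 0))
  expect_equal(sum(nv * c(100, 64)), objectVolume(o1) + objectVolume(o2))
})

test_that("volume conservation: object volumes sum to voxel volume times foreground", {
  set.seed(17)
  for (i in 1:5) {
    shapes <- list(sphereShape(c(3, 3, 3), runif(1, 0.8, 1.4)),
                   ellipsoidShape(c(3, 7.5, 7), runif(3, 0.7, 1.6)))
    g <- generateStack(stackSpec(shapeZyx = c(16, 44, 44), shapes = shapes),
                       seed = i)
    thr <- autoThreshold(as.numeric(voxelData(g$stack, "mito_green")))
    objs <- segmentObjects(g$stack, "mito_green", threshold = thr)
    total <- sum(vapply(objs, objectVolume, numeric(1)))
    fg <- sum(voxelData(g$stack, "mito_green") > thr)
    expect_equal(total, fg * prod(voxelSize(g$stack)))
  }
})
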