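test_that("stacks round-trip losslessly with metadata", {
  g <- generateStack(stackSpec(shapeZyx = c(8, 10, 12),
                               shapes = list(sphereShape(c(1.2, 1.2, 1.4), 0.8)),
                               gaussianSd = 1), seed = 2)
  path <- tempfile(fileext = ".tif")
  writeStack(g$stack, path)
  rt <- readStack(path)
  expect_identical(voxelData(rt), voxelData(g$stack))
  expect_equal(voxelSize(rt), c(0.34, 0.24, 0.24))  # anisotropic z-step kept
  expect_identical(channelRoles(rt), channelRoles(g$stack))
  expect_equal(bitMax(rt), 4095)
})

test_that("degenerate and mismatched stacks are handled", {
  # all-zero stack round-trips
  empty <- ImageStack(array(0, c(2, 3, 4, 4)), voxelSize = c(1, 1, 1),
                      channelRoles = c(th = 1L, mito_green = 2L),
                      bitMax = 4095)
  path <- tempfile(fileext = ".tif")
  writeStack(empty, path)
  expect_identical(voxelData(readStack(path)), voxelData(empty))
  # channel map demanding a role beyond the file's channels errors by name
  expect_error(
    readStack(path, channelMap = c(th = 1L, mito_green = 2L,
                                   red_reporter = 3L)),
    "red_reporter")
  expect_error(readStack(tempfile()), "no such file")
})

test_that("beam tables round-trip and validate", {
  series <- lapply(1:16, function(i)
    generateBeamSeries(beamSpec(durationS = 1200), seed = i,
                       tubeId = sprintf("t%02d", i))$series)
  path <- tempfile(fileext = ".csv")
  writeBeamTable(series, path)
  rt <- readBeamTable(path)
  expect_length(rt, 16)  # one series per monitored tube
  expect_identical(beamIndices(rt[[1]]), beamIndices(series[[1]]))
  expect_equal(length(beamIndices(rt[[7]])), 1200)

  tab <- utils::read.csv(path)
  tab$beam_index[5] <- 18L
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path2, row.names = FALSE)
  expect_error(readBeamTable(path2), "out of range")

  tab <- utils::read.csv(path)
  tab <- tab[tab$second != 10 | tab$tube_id != "t01", ]
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path3, row.names = FALSE)
  expect_error(readBeamTable(path3), "contiguous")
})

test_that("ImageStack and BeamEventSeries validity catches contract violations", {
  expect_error(ImageStack(array(-1, c(1, 2, 2, 2)), c(1, 1, 1),
                          c(th = 1L)), "non-negative")
  expect_error(ImageStack(array(1, c(1, 2, 2, 2)), c(1, 0, 1),
                          c(th = 1L)), "positive")
  expect_error(BeamEventSeries(c(1, 18), nBeams = 17), "1, nBeams")
  expect_silent(BeamEventSeries(c(1, 17), nBeams = 17))
})
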