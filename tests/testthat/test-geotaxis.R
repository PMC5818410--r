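test_that("beam positions map to millimetres via the 17-beam / 51 mm geometry", {
  s <- BeamEventSeries(c(1, 17, 2), nBeams = 17, spanMm = 51)
  tr <- buildTrace(s)
  expect_equal(as.numeric(tr), c(0, 51, 3.1875))
  expect_equal(attr(tr, "spacing"), 51 / 16)
  flat <- buildTrace(BeamEventSeries(rep(9, 30)))
  expect_true(all(flat == flat[1]))
})

test_that("climb extraction follows the ascending-run rule (hand trace)", {
  tr <- c(0, 3.1875, 9.5625, 6.375, 6.375, 12.75)
  climbs <- extractClimbs(tr)
  expect_equal(climbs, c(9.5625, 6.375))
  cs <- climbSummary(climbs)
  expect_equal(cs$totalHeight, 15.9375)
  expect_equal(cs$nClimbs, 2)
  expect_equal(cs$averageHeight, 7.96875)
  expect_equal(length(extractClimbs(c(10, 8, 8, 5, 1))), 0)
  expect_equal(extractClimbs(seq(0, 51, length.out = 18)), 51)
  empty <- climbSummary(numeric(0))
  expect_equal(c(empty$totalHeight, empty$nClimbs, empty$averageHeight),
               c(0, 0, 0))
  expect_true(empty$zeroClimbs)
})

test_that("total height equals the positive-displacement sum on random traces", {
  set.seed(23)
  for (i in 1:200) {
    tr <- cumsum(sample(c(-2, -1, 0, 1, 2), sample(5:60, 1), replace = TRUE))
    expect_equal(sum(extractClimbs(tr)), sum(pmax(diff(tr), 0)))
  }
})

test_that("ROC AUC equals pairwise concordance; Youden threshold classifies", {
  r <- rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75)
  sep <- rocCurve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$sensitivity, 1.0)
  expect_equal(sep$specificity, 1.0)
  same <- rocCurve(rep(c(1, 2, 3), 2), rep(c(0, 1), each = 3))
  expect_equal(same$auc, 0.5)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(41)
  for (i in 1:20) {
    sc <- sample(1:8, 25, replace = TRUE)  # ties on purpose
    lb <- runif(25) < 0.4
    if (all(lb) || !any(lb)) next
    expect_equal(rocCurve(sc, lb)$auc, aucPairs(sc, lb))
  }
})

test_that("climber classification uses >= and recovers the generator labels", {
  expect_false(classifyClimbers(data.frame(averageHeight = 0), 3))
  expect_true(classifyClimbers(data.frame(averageHeight = 3), 3))
  bc <- generateBeamCohort(25, 25, seed = 5)
  summ <- do.call(rbind, lapply(bc$series, function(s)
    climbSummary(extractClimbs(buildTrace(s)))))
  roc <- rocCurve(summ$averageHeight, bc$labels)
  acc <- mean(classifyClimbers(summ, roc$threshold) == bc$labels)
  expect_gte(acc, 0.95)
  # classification counts conserve group sizes in the Fisher table
  tab <- table(bc$labels, classifyClimbers(summ, roc$threshold))
  expect_equal(unname(rowSums(tab)), c(25, 25))
})
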