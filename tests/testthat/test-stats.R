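test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisherExact2x2(rbind(c(3, 1), c(1, 3)))$p, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(rbind(c(4, 0), c(0, 4)))$p, 2 / 70,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(rbind(c(3, 3), c(3, 3)))$p, 1.0)
  deg <- fisherExact2x2(rbind(c(0, 0), c(2, 5)))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  set.seed(13)
  for (i in 1:30) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact2x2(tab)$p, fisherBrute(tab), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches full-enumeration p for small samples", {
  expect_equal(mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mannWhitneyExact(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  set.seed(14)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    v <- sample(1:50, na + nb)  # unique values: exact branch
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    res <- mannWhitneyExact(a, b)
    expect_true(res$exact)
    expect_equal(res$p, mwBrute(a, b), tolerance = 1e-9)
  }
})

test_that("pooled t-test matches hand computation and is shift invariant", {
  r <- unpairedT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.021312, tolerance = 1e-4)
  expect_equal(unpairedT(c(1, 2, 3), c(2, 1, 3))$statistic, 0)
  expect_equal(unpairedT(c(1, 2, 3), c(2, 1, 3))$p, 1)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(unpairedT(a, b)$statistic, unpairedT(a + 5, b + 5)$statistic)
  expect_warning(dg <- unpairedT(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(dg$p, 1)
})

test_that("normality gate routes correctly and Dunnett adjustment is sound", {
  set.seed(2)
  v <- c(rnorm(15), rnorm(15), rnorm(15, 3))
  g <- rep(c("control", "a", "b"), each = 15)
  res <- normalityGateCompare(v, g, "control")
  expect_equal(attr(res, "branch"), "parametric")
  expect_lt(res$pAdj[res$comparison == "b - control"], 0.001)
  expect_gt(res$pAdj[res$comparison == "a - control"], 0.05)
  # adjusted p >= raw p, and monotone in raw p within the family
  expect_true(all(res$pAdj >= res$p - 1e-12))
  expect_equal(order(res$p), order(res$pAdj))

  # strongly lognormal data route to the nonparametric branch
  set.seed(3)
  frac <- mean(replicate(20, {
    v <- rlnorm(150, 0, 1)
    g <- rep(c("control", "a", "b"), each = 50)
    attr(normalityGateCompare(v, g, "control"), "branch") == "nonparametric"
  }))
  expect_gte(frac, 0.9)

  set.seed(8)
  expect_warning(
    res2 <- normalityGateCompare(rnorm(8), c("control", "control", "a", "a",
                                             "a", "b", "b", "b"), "control"),
    "n < 3")
  expect_equal(attr(res2, "branch"), "nonparametric")
})

test_that("gated procedure holds its family-wise type-I level on Gaussian nulls", {
  set.seed(4)
  rej <- mean(replicate(400, {
    v <- rnorm(45)
    g <- rep(c("control", "a", "b"), each = 15)
    any(normalityGateCompare(v, g, "control")$pAdj < 0.05)
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("two-way ANOVA matches a hand-computed balanced table", {
  # 2x2 balanced, 2 reps: sums of squares by the textbook formulas
  y <- c(3, 5, 6, 8, 10, 12, 13, 15)
  A <- rep(c("control", "mut"), each = 4)
  B <- rep(rep(c("5", "10"), each = 2), 2)
  grand <- mean(y)
  ssA <- 4 * sum((tapply(y, A, mean) - grand)^2)
  ssB <- 4 * sum((tapply(y, B, mean) - grand)^2)
  tw <- twoWayCompare(y, A, B, "control", "5")
  fit <- aov(y ~ factor(A) * factor(B))
  an <- anova(fit)
  expect_equal(an[["Sum Sq"]][1], ssA, tolerance = 1e-9)
  expect_equal(an[["Sum Sq"]][2], ssB, tolerance = 1e-9)
  expect_equal(tw$anova$Fvalue, an[["F value"]][1:3], tolerance = 1e-9)

  set.seed(5)
  d <- expand.grid(g = c("control", "het", "hom"), day = c("5", "10", "20"),
                   rep = 1:6)
  d$y <- rnorm(nrow(d)) + 2.5 * (d$g == "hom")
  tw2 <- twoWayCompare(d$y, d$g, d$day, "control", "5")
  expect_lt(tw2$anova$p[1], 0.001)
  expect_gt(tw2$anova$p[2], 0.05)
  expect_lt(tw2$comparisons$pAdj[tw2$comparisons$comparison ==
                                   "hom - control"], 0.001)
  keep <- !(d$g == "hom" & d$day == "20")
  expect_error(twoWayCompare(d$y[keep], d$g[keep], d$day[keep],
                             "control", "5"), "empty")
})

test_that("extreme-bin contingency tables are built and conserved", {
  hA <- list(counts = c(3L, 1L, 1L))
  hB <- list(counts = c(1L, 1L, 3L))
  tabs <- binDistributionTables(hA, hB)
  expect_equal(unname(tabs$small), rbind(c(3, 2), c(1, 4)))
  expect_equal(unname(tabs$large), rbind(c(1, 4), c(3, 2)))
  expect_equal(unname(rowSums(tabs$small)), c(5, 5))
  same <- binDistributionTables(hA, hA)
  expect_equal(fisherExact2x2(same$small)$p, 1.0)
})

test_that("experiment summaries are deterministic and validated", {
  set.seed(6)
  m <- data.frame(region = rep(c("PPL1", "PPM3"), each = 30),
                  group = rep(rep(c("control", "hom"), each = 15), 2),
                  meanVolume = rnorm(60, 10))
  m$meanVolume[m$region == "PPL1" & m$group == "hom"] <-
    m$meanVolume[m$region == "PPL1" & m$group == "hom"] + 5
  des <- list(control = "control", measures = "meanVolume")
  r1 <- summarizeExperiment(m, des)
  r2 <- summarizeExperiment(m, des)
  expect_identical(r1, r2)
  expect_true(r1$significant[r1$region == "PPL1"])
  expect_false(r1$significant[r1$region == "PPM3"])
  expect_true(all(r1$stars == pStars(r1$pAdj)))
  expect_error(summarizeExperiment(m, list(control = "control",
                                           measures = "nope")), "lacks")
})
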