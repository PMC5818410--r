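#' Significance stars
#'
#' Star coding used throughout the study's figures: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p numeric p-values.
#' @return Character vector of star strings ("" when p >= 0.05).
#' @export
pStars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

# Dunn's post-hoc rank comparisons to control after Kruskal-Wallis,
# with tie correction and Holm adjustment across the control comparisons.
.dunnToControl <- function(values, groups, control) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieCorr
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  others <- setdiff(names(rbar), control)
  z <- vapply(others, function(g) {
    (rbar[[g]] - rbar[[control]]) /
      sqrt(s2 * (1 / n[[g]] + 1 / n[[control]]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  data.frame(comparison = paste(others, "-", control),
             statistic = as.numeric(z), p = as.numeric(p),
             pAdj = p.adjust(p, "holm"))
}

#' Normality-gated comparisons to a control group
#'
#' The study's default comparison procedure: Shapiro-Wilk is applied to each
#' group (at `gateAlpha`); if every group passes, a one-way ANOVA with
#' Dunnett's multiple-comparisons test against the control is used, otherwise
#' a Kruskal-Wallis test followed by Dunn's comparisons to control (Holm
#' adjusted). Groups too small for Shapiro-Wilk (n < 3) or constant route the
#' whole family to the nonparametric branch with a warning.
#'
#' @param values numeric measurements.
#' @param groups group labels (same length); must include `control`.
#' @param control the control group label.
#' @param gateAlpha Shapiro-Wilk significance level for the gate.
#' @return data.frame with one row per comparison to control: `comparison`,
#'   `test`, `statistic`, `p` (unadjusted), `pAdj` (Dunnett- or
#'   Holm-adjusted), `stars`. Attributes: `branch`
#'   ("parametric"/"nonparametric"), `overall` (list with the ANOVA F or
#'   Kruskal-Wallis statistic and p), `shapiroP` (per-group gate p-values).
#' @export
normalityGateCompare <- function(values, groups, control,
                                 gateAlpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ug <- unique(groups)
  if (length(ug) < 2) stop("need at least 2 groups")
  if (!control %in% ug) stop("control group '", control, "' not present")
  split_ <- split(values, groups)
  ns <- vapply(split_, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")

  shapiroP <- rep(NA_real_, length(split_))
  names(shapiroP) <- names(split_)
  forcedNonpar <- FALSE
  for (g in names(split_)) {
    v <- split_[[g]]
    if (length(v) < 3) {
      warning("group '", g, "' has n < 3: Shapiro-Wilk not applicable, ",
              "routing to nonparametric branch")
      forcedNonpar <- TRUE
    } else if (length(unique(v)) == 1) {
      shapiroP[g] <- 0  # constant: treat as failing normality
    } else {
      shapiroP[g] <- shapiro.test(v)$p.value
    }
  }
  parametric <- !forcedNonpar && all(shapiroP > gateAlpha, na.rm = FALSE)

  gf <- factor(groups, levels = c(control, setdiff(sort(ug), control)))
  if (parametric) {
    dat <- data.frame(y = values, g = gf)
    fit <- aov(y ~ g, data = dat)
    an <- anova(fit)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    # multivariate-t probabilities are quasi-Monte Carlo: fix the stream so
    # identical input gives an identical report
    smAdj <- withr::with_seed(1L, summary(gl))
    smRaw <- withr::with_seed(1L,
      summary(gl, test = multcomp::adjusted("none")))
    res <- data.frame(
      comparison = names(smAdj$test$coefficients),
      test = "one-way ANOVA + Dunnett",
      statistic = as.numeric(smAdj$test$tstat),
      p = as.numeric(smRaw$test$pvalues),
      pAdj = as.numeric(smAdj$test$pvalues))
    overall <- list(test = "one-way ANOVA",
                    statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1])
  } else {
    kw <- kruskal.test(values, gf)
    res <- .dunnToControl(values, groups, control)
    res <- data.frame(comparison = res$comparison,
                      test = "Kruskal-Wallis + Dunn (Holm)",
                      statistic = res$statistic, p = res$p, pAdj = res$pAdj)
    overall <- list(test = "Kruskal-Wallis", statistic = kw$statistic,
                    p = kw$p.value)
  }
  res$stars <- pStars(res$pAdj)
  rownames(res) <- NULL
  attr(res, "branch") <- if (parametric) "parametric" else "nonparametric"
  attr(res, "overall") <- overall
  attr(res, "shapiroP") <- shapiroP
  res
}

#' Two-way ANOVA with Dunnett comparisons to control levels
#'
#' Fits `y ~ A * B`, reports the main-effect and interaction p-values, and
#' compares the marginal means of each factor to its control level (e.g.
#' genotype to the wild type and day to day 5) with Dunnett-style
#' multiplicity adjustment (multivariate-t).
#'
#' @param values numeric measurements.
#' @param factorA,factorB factor labels (e.g. genotype, collection day).
#' @param controlA,controlB control level of each factor.
#' @param nameA,nameB names used in the output.
#' @return list with `anova` (data.frame of effects) and `comparisons`
#'   (data.frame: factor, comparison, estimate, statistic, pAdj, stars).
#'   Empty design cells are an error.
#' @export
twoWayCompare <- function(values, factorA, factorB, controlA, controlB,
                          nameA = "genotype", nameB = "day") {
  fA <- factor(as.character(factorA))
  fB <- factor(as.character(factorB))
  stopifnot(controlA %in% levels(fA), controlB %in% levels(fB))
  if (any(table(fA, fB) == 0)) stop("empty design cell")
  fA <- stats::relevel(fA, controlA)
  fB <- stats::relevel(fB, controlB)
  dat <- data.frame(y = values, A = fA, B = fB)
  fit <- aov(y ~ A * B, data = dat)
  an <- anova(fit)
  effects <- data.frame(
    effect = c(nameA, nameB, paste0(nameA, ":", nameB)),
    Fvalue = an[["F value"]][1:3],
    p = an[["Pr(>F)"]][1:3])

  cmpFor <- function(var, control, name) {
    # marginal means are compared deliberately (the interaction NOTE from
    # emmeans restates the design, not an error)
    emm <- suppressMessages(emmeans::emmeans(fit, specs = var))
    ct <- withr::with_seed(1L, summary(emmeans::contrast(
      emm, method = "trt.vs.ctrl",
      ref = which(levels(dat[[var]]) == control), adjust = "mvt")))
    data.frame(factor = name, comparison = ct$contrast,
               estimate = ct$estimate, statistic = ct$t.ratio,
               pAdj = ct$p.value, stars = pStars(ct$p.value))
  }
  comparisons <- rbind(cmpFor("A", controlA, nameA),
                       cmpFor("B", controlB, nameB))
  rownames(comparisons) <- NULL
  list(anova = effects, comparisons = comparisons)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p: the sum of hypergeometric probabilities (margins fixed)
#' of all tables at most as probable as the observed one. A zero margin is
#' degenerate and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p`, `oddsRatio`, `degenerate`.
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p  # 34/70
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)) || all(dim(tab) == 2))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, oddsRatio = NA_real_, degenerate = TRUE))
  ft <- fisher.test(tab)
  list(p = ft$p.value, oddsRatio = unname(ft$estimate), degenerate = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact permutation p-value for small samples (both n <= 10, no ties);
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `statistic` (W), `p`, `exact`.
#' @examples
#' mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 (= 2/20)
#' @export
mannWhitneyExact <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- length(a) <= 10 && length(b) <= 10 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return list with `statistic`, `df`, `p`, `degenerate` (TRUE when the
#'   pooled variance is zero, in which case p is 1 for equal means and 0
#'   otherwise).
#' @export
unpairedT <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    warning("zero pooled variance: degenerate t-test")
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Contingency tables for extreme size bins
#'
#' Builds, for the small and the large bin, the 2x2 table (group A vs B) x
#' (in-bin vs not-in-bin) used for Fisher's exact tests on the size frequency
#' distribution.
#'
#' @param histA,histB [sizeHistogram] results built under the same binning
#'   protocol.
#' @return list with `small` and `large` 2x2 matrices (rows = groups A, B;
#'   columns = in-bin, not-in-bin).
#' @export
binDistributionTables <- function(histA, histB) {
  totA <- sum(histA$counts)
  totB <- sum(histB$counts)
  mk <- function(i) {
    m <- rbind(A = c(histA$counts[i], totA - histA$counts[i]),
               B = c(histB$counts[i], totB - histB$counts[i]))
    colnames(m) <- c("in_bin", "not_in_bin")
    m
  }
  list(small = mk(1), large = mk(3))
}
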