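#' Specify a synthetic imaging cohort
#'
#' Describes a genotype-style cohort of z-stack clusters with group-level
#' effects on mitochondrial shape, size and reporter composition, emulating
#' the study's design (one cluster imaged per brain, >= 10 clusters per
#' condition). Each cluster is one TH-labelled region containing axis-aligned
#' spheroid mitochondria; per-cluster and per-object lognormal variability
#' provide the biological scatter, and group effects shift the generating
#' parameters.
#'
#' Two assay flavours share the geometry: `"mito"` nests a red (aged
#' MitoTimer-like) ellipsoid inside each green mitochondrion so the red:green
#' volume ratio is controlled by `baseRedFraction * redGreenScale`; `"puncta"`
#' instead scatters autophagosome-sized red puncta, a fraction of which
#' (`colocFraction`) are centred on mitochondria.
#'
#' @param groups group labels (first is conventionally the control).
#' @param nClustersPerGroup clusters (stacks) per group, >= 1.
#' @param effects named list of per-group effect lists; names must be group
#'   labels. Each effect list may set `aspect` (ellipsoid aspect ratio a:1:1,
#'   volume-preserving), `volumeScale` (multiplies true object volume),
#'   `redGreenScale` (multiplies the red fraction) and `colocFraction`
#'   (puncta assay). Unknown group names are an error.
#' @param region region label stamped into the truth table (e.g. "PPL1").
#' @param assay `"mito"` or `"puncta"` (see above).
#' @param nObjectsPerCluster mitochondrial objects per cluster.
#' @param baseRadius volume-equivalent object radius in um (true volume
#'   `4/3 pi r^3`).
#' @param baseAspect baseline aspect ratio (1 = spherical control).
#' @param baseRedFraction baseline red:green volume fraction (mito assay).
#' @param nPuncta red puncta per cluster (puncta assay).
#' @param colocFraction baseline colocalized fraction (puncta assay).
#' @param objectSdLog,clusterSdLog lognormal sd of per-object and per-cluster
#'   volume (and ratio) variability.
#' @param shapeZyx,voxelSizeZyx,psfSigmaZyx,poissonScale,gaussianSd stack
#'   geometry and noise, as in [stackSpec].
#' @return A `CohortSpec` list.
#' @export
cohortSpec <- function(groups = c("control", "het", "hom"),
                       nClustersPerGroup = 15L,
                       effects = list(),
                       region = "PPL1",
                       assay = c("mito", "puncta"),
                       nObjectsPerCluster = 6L,
                       baseRadius = 1.6,
                       baseAspect = 1,
                       baseRedFraction = 0.3,
                       nPuncta = 6L,
                       colocFraction = 0.5,
                       objectSdLog = 0.25,
                       clusterSdLog = 0.2,
                       shapeZyx = c(20L, 96L, 96L),
                       voxelSizeZyx = c(0.34, 0.24, 0.24),
                       psfSigmaZyx = c(0.44, 0.15, 0.15),
                       poissonScale = 1,
                       gaussianSd = 2) {
  assay <- match.arg(assay)
  if (nClustersPerGroup < 1) stop("nClustersPerGroup must be >= 1")
  unknown <- setdiff(names(effects), groups)
  if (length(unknown))
    stop("effects refer to unknown group label(s): ",
         paste(unknown, collapse = ", "))
  spec <- mget(setdiff(names(formals(cohortSpec)), "..."),
               envir = environment())
  class(spec) <- "CohortSpec"
  spec
}

.groupEffect <- function(spec, g) {
  e <- spec$effects[[g]]
  list(aspect = e$aspect %||% spec$baseAspect,
       volumeScale = e$volumeScale %||% 1,
       redGreenScale = e$redGreenScale %||% 1,
       colocFraction = e$colocFraction %||% spec$colocFraction)
}

# jittered grid of object centres inside the cluster region: guarantees that
# neighbouring objects stay resolvable (no 26-connected contact after PSF
# blurring) for every seed, unlike rejection sampling in a crowded field
.gridCenters <- function(center, n, gridW = 12.5, gridH = 11,
                         jitterXy = 0.5, jitterZ = 0.8) {
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  xs <- if (nx == 1) center[3] else
    center[3] + seq(-gridW / 2, gridW / 2, length.out = nx)
  ys <- if (ny == 1) center[2] else
    center[2] + seq(-gridH / 2, gridH / 2, length.out = ny)
  g <- expand.grid(y = ys, x = xs)[seq_len(n), ]
  cbind(z = center[1] + runif(n, -jitterZ, jitterZ),
        y = g$y + runif(n, -jitterXy, jitterXy),
        x = g$x + runif(n, -jitterXy, jitterXy))
}

# lognormal draw truncated at +/- 1.5 sd so object extents stay bounded
.rlnormTrunc <- function(sdlog) exp(pmin(pmax(rnorm(1, 0, sdlog),
                                              -1.5 * sdlog), 1.5 * sdlog))

# build the ShapeTruth list for one cluster
.clusterShapes <- function(spec, eff) {
  extent <- (spec$shapeZyx - 1) * spec$voxelSizeZyx
  center <- extent / 2
  thSemi <- pmin(c(2.6, 10.2, 10.2), extent / 2 - 0.4)
  n <- spec$nObjectsPerCluster
  clusterScale <- .rlnormTrunc(spec$clusterSdLog) * eff$volumeScale
  ratioScale <- .rlnormTrunc(spec$clusterSdLog) * eff$redGreenScale

  pts <- .gridCenters(center, n)
  green <- vector("list", n)
  for (j in seq_len(n)) {
    r <- spec$baseRadius *
      (clusterScale * .rlnormTrunc(spec$objectSdLog))^(1 / 3)
    a <- max(1, eff$aspect * .rlnormTrunc(0.08))
    # volume-preserving elongation along y (the grid's wide-spacing axis)
    semi <- c(r * a^(-1 / 3), r * a^(2 / 3), r * a^(-1 / 3))
    green[[j]] <- ellipsoidShape(pts[j, ], semi, intensity = 100,
                                 channel = "mito_green")
  }

  shapes <- green
  if (spec$assay == "mito") {
    for (j in seq_len(n)) {
      f <- min(0.92, spec$baseRedFraction * ratioScale * exp(rnorm(1, 0, 0.1)))
      vG <- green[[j]]$trueVolume
      if (f * vG < 1.15) f <- min(0.92, 1.15 / vG)  # keep red above puncta size
      if (f * vG < 1.05) next                        # green too small to host red
      red <- ellipsoidShape(green[[j]]$center,
                            green[[j]]$semiAxes * f^(1 / 3),
                            intensity = 100, channel = "red_reporter")
      shapes <- c(shapes, list(red))
    }
  }
  th <- ellipsoidShape(center, thSemi, intensity = 120, channel = "th")
  list(shapes = shapes, thSomas = list(th))
}

#' Generate a cohort of synthetic stacks with a tidy truth table
#'
#' @param spec a [cohortSpec].
#' @param seed master integer seed; stacks get derived sub-seeds, so the whole
#'   cohort is reproducible.
#' @return list with `stacks` (list of [generateStack] results, one per
#'   cluster) and `truth` (data.frame: group, cluster, region, trueMeanVolume,
#'   trueMeanInvSphericity, trueRatio, trueColocCount).
#' @export
generateCohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "CohortSpec"))
  nTot <- length(spec$groups) * spec$nClustersPerGroup
  withr::with_seed(as.integer(seed), {
    subSeeds <- sample.int(.Machine$integer.max - 1L, nTot)
    stacks <- vector("list", nTot)
    rows <- vector("list", nTot)
    k <- 0L
    for (g in spec$groups) {
      eff <- .groupEffect(spec, g)
      for (i in seq_len(spec$nClustersPerGroup)) {
        k <- k + 1L
        geom <- .clusterShapes(spec, eff)
        sspec <- stackSpec(
          shapeZyx = spec$shapeZyx, voxelSizeZyx = spec$voxelSizeZyx,
          shapes = geom$shapes, thSomas = geom$thSomas,
          psfSigmaZyx = spec$psfSigmaZyx,
          poissonScale = spec$poissonScale, gaussianSd = spec$gaussianSd,
          redPuncta = if (spec$assay == "puncta")
            list(n = spec$nPuncta, radius = 0.4, intensity = 150) else NULL,
          colocFraction = if (spec$assay == "puncta") eff$colocFraction else 0)
        stacks[[k]] <- generateStack(sspec, seed = subSeeds[k])
        tr <- stacks[[k]]$truth
        gV <- tr$trueVolume[tr$channel == "mito_green"]
        gS <- tr$trueInvSphericity[tr$channel == "mito_green"]
        rV <- tr$trueVolume[tr$channel == "red_reporter" &
                              tr$kind != "punctum"]
        rows[[k]] <- data.frame(
          group = g, cluster = k, region = spec$region,
          trueMeanVolume = mean(gV),
          trueMeanInvSphericity = mean(gS),
          trueRatio = if (spec$assay == "mito") sum(rV) / sum(gV)
                      else NA_real_,
          trueColocCount = if (spec$assay == "puncta")
            sum(tr$isColoc) else NA_integer_)
      }
    }
    list(stacks = stacks, truth = do.call(rbind, rows))
  })
}
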