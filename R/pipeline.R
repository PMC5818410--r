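#' Quantify one z-stack cluster end to end
#'
#' Runs the full measurement pipeline on one stack: builds the TH ROI and soma
#' labels, Otsu-thresholds the green channel inside the ROI, segments
#' 26-connected mitochondrial objects and keeps those with centroids inside
#' the ROI, computes per-object morphometrics, repeats segmentation for the
#' red reporter channel, derives MitoTimer-style total volumes and the
#' red:green ratio, filters autophagosome-sized red puncta, counts puncta
#' colocalized with the green channel, and computes mitochondrial network
#' volume per cell.
#'
#' @param stack an [ImageStack-class] with roles `th`, `mito_green`,
#'   `red_reporter`.
#' @param minSomaVolume minimum soma volume for [buildRoi] (um^3).
#' @param punctaBounds autophagosome volume bounds (um^3), `(vMin, vMax]`.
#' @param connectivity object connectivity (26 or 6).
#' @return list with `roi`, `greenObjects`, `redObjects`, `puncta`,
#'   `metrics` (per green object), `networkVolumePerCell`, `coloc` and a
#'   one-row `summary` data.frame (nObjects, meanVolume, meanInvSphericity,
#'   totalGreenVolume, totalRedVolume, redGreenRatio, nPuncta, nCells,
#'   punctaPerCell, nColoc, meanNetworkVolumePerCell).
#' @export
quantifyCluster <- function(stack, minSomaVolume = 30,
                            punctaBounds = c(0.1, 1), connectivity = 26L) {
  roi <- buildRoi(stack, minSomaVolume = minSomaVolume)
  green <- segmentObjects(stack, "mito_green", roi = roi,
                          connectivity = connectivity)
  green <- restrictToRoi(green, roi)
  red <- segmentObjects(stack, "red_reporter", roi = roi,
                        connectivity = connectivity)
  red <- restrictToRoi(red, roi)
  metrics <- objectMetrics(green)
  totalGreen <- totalChannelVolume(green)
  totalRed <- totalChannelVolume(red)
  ratio <- if (totalGreen > 0) totalRed / totalGreen else NA_real_
  puncta <- filterPuncta(red, punctaBounds[1], punctaBounds[2])
  k <- nCells(roi)
  coloc <- countColocalized(puncta, nCells = if (k > 0) k else NULL)
  nvpc <- if (k >= 1) networkVolumePerCell(green, roi) else numeric(0)
  summary <- data.frame(
    nObjects = length(green),
    meanVolume = if (length(green)) mean(metrics$volume) else NA_real_,
    meanInvSphericity = if (length(green)) mean(metrics$inverseSphericity)
                        else NA_real_,
    totalGreenVolume = totalGreen,
    totalRedVolume = totalRed,
    redGreenRatio = ratio,
    nPuncta = length(puncta),
    nCells = k,
    punctaPerCell = if (k > 0) length(puncta) / k else NA_real_,
    nColoc = coloc$nColocalized,
    meanNetworkVolumePerCell = if (length(nvpc)) mean(nvpc) else NA_real_)
  list(roi = roi, greenObjects = green, redObjects = red, puncta = puncta,
       metrics = metrics, networkVolumePerCell = nvpc, coloc = coloc,
       summary = summary)
}

#' Measure every cluster of a synthetic cohort
#'
#' Applies [quantifyCluster] to each generated stack and binds the per-cluster
#' summaries with the cohort's group/region keys, giving the table the
#' statistics layer consumes.
#'
#' @param cohort output of [generateCohort].
#' @param ... passed to [quantifyCluster].
#' @return data.frame: one row per cluster with group, cluster, region and the
#'   measured summary columns.
#' @export
measureCohort <- function(cohort, ...) {
  rows <- lapply(seq_along(cohort$stacks), function(i) {
    q <- quantifyCluster(cohort$stacks[[i]]$stack, ...)
    cbind(cohort$truth[i, c("group", "cluster", "region")], q$summary)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
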