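#' Total segmented volume of a channel
#'
#' Sum of the per-object volumes, e.g. the total MitoTimer red (aged) or green
#' (newly synthesized) volume of a cluster.
#'
#' @param objects list of [SegmentedObject-class] from one channel/cluster.
#' @return Total volume in um^3 (0 for an empty list).
#' @export
totalChannelVolume <- function(objects) {
  if (length(objects) == 0L) return(0)
  sum(vapply(objects, objectVolume, numeric(1)))
}

#' MitoTimer red:green volume ratio
#'
#' Ratio of total red (oxidized, aged) to total green (newly synthesized)
#' reporter volume per cluster; a rising ratio indexes slowed mitochondrial
#' turnover. Zero green volume makes the ratio undefined (`NA` with attribute
#' `undefined = TRUE`); such clusters are excluded from statistics.
#'
#' @param redTotal,greenTotal total volumes (um^3), >= 0.
#' @return `redTotal / greenTotal`, or flagged `NA`.
#' @export
redGreenRatio <- function(redTotal, greenTotal) {
  stopifnot(redTotal >= 0, greenTotal >= 0)
  if (greenTotal == 0) {
    warning("green total volume is 0: red:green ratio undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  redTotal / greenTotal
}

#' Filter autophagosome-sized puncta
#'
#' Keeps objects with `vMin < volume <= vMax`. The study counted red
#' (mCherry-atg8a) objects between 0.1 and 1 cubic micrometre; the printed
#' lower bound of "0.1 nm^3" is ten orders of magnitude below a voxel and is
#' read as 0.1 um^3 (both bounds configurable).
#'
#' @param objects list of [SegmentedObject-class].
#' @param vMin exclusive lower volume bound (um^3).
#' @param vMax inclusive upper volume bound (um^3).
#' @return Filtered list.
#' @export
filterPuncta <- function(objects, vMin = 0.1, vMax = 1.0) {
  if (length(objects) == 0L) return(objects)
  v <- vapply(objects, objectVolume, numeric(1))
  objects[v > vMin & v <= vMax]
}

#' Autophagosome puncta per cell
#'
#' @param nPuncta number of puncta within TH-labelled somata.
#' @param nCells number of TH-positive neurons (> 0).
#' @return `nPuncta / nCells`.
#' @export
punctaPerCell <- function(nPuncta, nCells) {
  if (nCells == 0) stop("nCells must be >= 1")
  stopifnot(nPuncta >= 0)
  nPuncta / nCells
}

#' Object-based Pearson correlation between two channels
#'
#' Pearson correlation of the two channels' intensities over the object's
#' voxels. Undefined (`NA`) when the object has fewer than 2 voxels or either
#' channel is constant over the object.
#'
#' @param obj a [SegmentedObject-class] carrying intensities for both roles.
#' @param roleA,roleB channel role names.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
objectPearson <- function(obj, roleA = "red_reporter",
                          roleB = "mito_green") {
  ints <- objectIntensities(obj)
  if (!all(c(roleA, roleB) %in% colnames(ints)))
    stop("object does not carry intensities for both roles")
  a <- ints[, roleA]
  b <- ints[, roleB]
  if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Count red objects colocalized with the green channel
#'
#' An object counts as colocalized (mitophagy initiation) when the Pearson
#' correlation between its red and green intensities exceeds `rThreshold`
#' (default 0 -- literally "a positive Pearson's correlation coefficient"). Undefined correlations (constant green signal,
#' i.e. a punctum over no mitochondrial signal) count as not colocalized.
#'
#' @param redObjects list of [SegmentedObject-class] (red channel), each
#'   carrying green intensities.
#' @param greenRole,redRole channel role names.
#' @param nCells optional cell count for a per-cell normalization.
#' @param rThreshold minimum correlation to call colocalization.
#' @return list with `nRedObjects`, `nColocalized`, `perCell` (NA when
#'   `nCells` not given), and `r` (the per-object correlations).
#' @export
countColocalized <- function(redObjects, greenRole = "mito_green",
                             redRole = "red_reporter", nCells = NULL,
                             rThreshold = 0) {
  r <- vapply(redObjects, objectPearson, numeric(1),
              roleA = redRole, roleB = greenRole)
  n <- sum(!is.na(r) & r > rThreshold)
  list(nRedObjects = length(redObjects),
       nColocalized = n,
       perCell = if (is.null(nCells)) NA_real_ else n / nCells,
       r = r)
}
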