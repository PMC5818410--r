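#' Otsu automatic intensity threshold
#'
#' Threshold maximizing the between-class variance of the intensity histogram
#' (Otsu). For integer-valued data with a range up to 65536 levels the
#' histogram is exact (one bin per integer level, so the result equals an
#' exhaustive search over all candidate levels); otherwise 256 equal-width
#' bins are used. Foreground is `intensity > threshold`.
#'
#' @param x numeric vector of intensities (e.g. the voxels inside the ROI).
#' @param nbins bins used for non-integer data.
#' @return The threshold (numeric). Constant input returns `NA` with a warning
#'   and attribute `degenerate = TRUE` (empty foreground).
#' @examples
#' autoThreshold(c(rep(10, 90), rep(200, 10)))  # strictly inside (10, 200)
#' @export
autoThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty intensity sample")
  if (min(x) == max(x)) {
    warning("constant intensities: degenerate threshold, empty foreground")
    return(structure(NA_real_, degenerate = TRUE))
  }
  isInt <- all(x == round(x)) && (max(x) - min(x)) <= 65536
  if (isInt) {
    lev <- seq(min(x), max(x))
    h <- tabulate(x - min(x) + 1L, nbins = length(lev))
  } else {
    br <- seq(min(x), max(x), length.out = nbins + 1L)
    h <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                  nbins = nbins)
    lev <- (br[-length(br)] + br[-1]) / 2
  }
  lev <- lev[h > 0]  # the variance only changes at occupied levels
  h <- h[h > 0]
  n <- sum(h)
  w0 <- cumsum(h) / n
  mu <- cumsum(h * lev) / n
  muT <- mu[length(mu)]
  # between-class variance for class0 = levels <= t (all t except the last);
  # the returned threshold is the midpoint to the next occupied level, so it
  # falls strictly between the separated classes
  k <- length(lev) - 1L
  w0 <- w0[seq_len(k)]
  mu0 <- mu[seq_len(k)]
  sb <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  best <- which.max(sb)
  (lev[best] + lev[best + 1L]) / 2
}

# shift-based binary dilation/erosion with a 3x3x3 cube (26-neighbourhood)
.dilate3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- intersect(seq_len(d[1]), seq_len(d[1]) - dz)
    sy <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
    sx <- intersect(seq_len(d[3]), seq_len(d[3]) - dx)
    out[sz + dz, sy + dy, sx + dx] <-
      out[sz + dz, sy + dy, sx + dx] | mask[sz, sy, sx]
  }
  out
}

.erode3d <- function(mask) !.dilate3d(!mask)

.close3d <- function(mask) .erode3d(.dilate3d(mask))

#' Label 3D connected components
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (voxels sharing a face, edge or corner are
#'   connected; the default, matching the visual connectedness of thin
#'   tubules) or 6 (faces only).
#' @return Integer array of the same shape: 0 background, k for component k;
#'   attribute `n` holds the component count.
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  lab <- .cpp_label_components(as.logical(mask), dim(mask),
                               as.integer(connectivity))
  n <- attr(lab, "n")
  lab <- array(lab, dim(mask))
  attr(lab, "n") <- n
  lab
}

#' Build the TH region of interest and soma labels
#'
#' Otsu-thresholds the TH channel, applies a binary closing with a one-voxel
#' (26-neighbourhood) ball to bridge staining gaps, and takes the result as
#' the ROI. Somata are the 26-connected components of the ROI whose volume
#' exceeds `minSomaVolume`; touching somata are not split.
#'
#' @param stack an [ImageStack-class].
#' @param thRole role name of the TH channel.
#' @param minSomaVolume minimum soma volume in um^3 (default 30).
#' @return A [RoiMask-class]. With no TH signal, an empty ROI (0 cells) and a
#'   warning.
#' @export
buildRoi <- function(stack, thRole = "th", minSomaVolume = 30) {
  th <- voxelData(stack, thRole)
  thr <- suppressWarnings(autoThreshold(as.numeric(th)))
  d <- dim(th)
  if (is.na(thr) || !any(th > thr)) {
    warning("no TH signal: empty ROI")
    return(new("RoiMask", mask = array(FALSE, d),
               somaLabels = array(0L, d), somaVolumes = numeric(0),
               voxelSize = voxelSize(stack)))
  }
  mask <- .close3d(th > thr)
  lab <- labelComponents(mask, 26L)
  nLab <- attr(lab, "n")
  voxVol <- prod(voxelSize(stack))
  counts <- tabulate(lab[lab > 0], nbins = nLab)
  keep <- which(counts * voxVol >= minSomaVolume)
  somaLab <- array(0L, d)
  for (i in seq_along(keep))
    somaLab[lab == keep[i]] <- i
  new("RoiMask", mask = mask, somaLabels = somaLab,
      somaVolumes = counts[keep] * voxVol,
      voxelSize = voxelSize(stack))
}

#' Segment 3D objects above a threshold
#'
#' Thresholds one channel (`intensity > threshold`) and extracts connected
#' components. Each object carries the intensities of all channels at its
#' voxels so colocalization can be computed downstream. The union of object
#' voxels equals the foreground mask exactly.
#'
#' @param stack an [ImageStack-class].
#' @param role channel role to segment.
#' @param threshold intensity threshold; if `NULL`, computed by
#'   [autoThreshold] from the channel voxels inside `roi` (or the whole
#'   channel when no ROI is given).
#' @param roi optional [RoiMask-class] used only to restrict the voxels from
#'   which an automatic threshold is computed; objects are *not* clipped to
#'   the ROI here (see [restrictToRoi]).
#' @param connectivity 26 (default) or 6.
#' @return List of [SegmentedObject-class]; empty foreground gives an empty
#'   list.
#' @export
segmentObjects <- function(stack, role, threshold = NULL, roi = NULL,
                           connectivity = 26L) {
  chan <- voxelData(stack, role)
  if (is.null(threshold)) {
    vals <- if (is.null(roi)) as.numeric(chan) else as.numeric(chan[roiMask(roi)])
    threshold <- autoThreshold(vals)
  }
  if (is.na(threshold)) return(list())
  stopifnot(is.finite(threshold))
  mask <- chan > threshold
  if (!any(mask)) return(list())
  lab <- labelComponents(mask, connectivity)
  n <- attr(lab, "n")
  idx <- which(lab > 0)
  labs <- lab[idx]
  d <- dim(mask)
  z <- ((idx - 1L) %% d[1]) + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  roles <- channelRoles(stack)
  inten <- matrix(0, length(idx), length(roles),
                  dimnames = list(NULL, names(roles)))
  for (r in names(roles)) {
    cc <- voxelData(stack, r)
    inten[, r] <- cc[idx]
  }
  ord <- split(seq_along(idx), labs)
  lapply(ord, function(i) {
    new("SegmentedObject", channel = role,
        coords = cbind(z = z[i], y = y[i], x = x[i]),
        intensities = inten[i, , drop = FALSE],
        voxelSize = voxelSize(stack))
  })
}

#' Keep objects whose centroid lies inside the ROI
#'
#' Membership is decided by the object centroid (rounded to the nearest
#' voxel), so objects straddling the ROI boundary are kept whole or dropped
#' whole rather than fragmented.
#'
#' @param objects list of [SegmentedObject-class].
#' @param roi a [RoiMask-class] with the same dimensions as the source stack.
#' @return The filtered list.
#' @export
restrictToRoi <- function(objects, roi) {
  stopifnot(is(roi, "RoiMask"))
  m <- roiMask(roi)
  d <- dim(m)
  keep <- vapply(objects, function(o) {
    ctr <- pmin(pmax(round(objectCentroid(o)), 1L), d)
    m[ctr[1], ctr[2], ctr[3]]
  }, logical(1))
  objects[keep]
}

#' Fraction of saturated voxels (overexposure QC)
#'
#' The study's capture protocol aimed for about 2% of the image overexposed;
#' a fraction outside `band * target` raises a QC warning.
#'
#' @param stack an [ImageStack-class].
#' @param role channel role to check.
#' @param target intended overexposed fraction (default 0.02).
#' @param band acceptable multiplicative band around `target`.
#' @return Fraction of voxels at `bitMax`, in `[0, 1]`.
#' @export
saturationFraction <- function(stack, role, target = 0.02,
                               band = c(0.5, 2)) {
  chan <- voxelData(stack, role)
  f <- mean(chan >= bitMax(stack))
  if (!is.null(target) && (f < band[1] * target || f > band[2] * target))
    warning(sprintf(
      "saturation fraction %.4f outside QC band [%.4f, %.4f] for '%s'",
      f, band[1] * target, band[2] * target, role))
  f
}
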