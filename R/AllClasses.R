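#' ImageStack: a multi-channel 3D intensity volume
#'
#' Container for a confocal z-stack. Voxel data are stored as a 4D array
#' indexed `[channel, z, y, x]` with physical voxel dimensions in micrometres
#' (z, y, x order) and a named map from channel roles (`th`, `mito_green`,
#' `red_reporter`) to channel indices. `bitMax` is the detector saturation
#' intensity; voxels at `bitMax` are considered overexposed.
#'
#' @slot voxels 4D numeric array `[channel, z, y, x]`, non-negative.
#' @slot voxelSize numeric(3), micrometres per voxel along (z, y, x); all > 0.
#' @slot channelRoles named integer vector mapping role names to channel
#'   indices.
#' @slot bitMax numeric(1), saturation intensity (all voxels are <= bitMax).
#'
#' @examples
#' spec <- stackSpec(shapeZyx = c(12, 24, 24),
#'                   shapes = list(sphereShape(c(2, 3, 3), 1, channel = "mito_green")))
#' g <- generateStack(spec, seed = 1)
#' stack <- g$stack
#' dim(voxelData(stack, "mito_green"))
#' @name ImageStack-class
#' @aliases ImageStack
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    voxels = "array",
    voxelSize = "numeric",
    channelRoles = "integer",
    bitMax = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 4L)
    msg <- c(msg, "voxels must be a 4D array [channel, z, y, x]")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values (z, y, x)")
  if (is.null(names(object@channelRoles)) ||
      any(!nzchar(names(object@channelRoles))))
    msg <- c(msg, "channelRoles must be named")
  if (length(d) == 4L &&
      (any(object@channelRoles < 1L) || any(object@channelRoles > d[1])))
    msg <- c(msg, "channelRoles indices out of range")
  if (length(object@bitMax) != 1L || object@bitMax <= 0)
    msg <- c(msg, "bitMax must be a single positive value")
  if (any(object@voxels < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (max(object@voxels) > object@bitMax)
    msg <- c(msg, "intensities exceed bitMax")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 4D numeric array `[channel, z, y, x]`.
#' @param voxelSize micrometres per voxel, (z, y, x).
#' @param channelRoles named integer vector (role -> channel index).
#' @param bitMax saturation intensity; defaults to the smallest of 255, 4095,
#'   65535 that accommodates the data.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(voxels, voxelSize, channelRoles,
                       bitMax = NULL) {
  if (is.null(bitMax)) {
    m <- max(voxels)
    bitMax <- if (m <= 255) 255 else if (m <= 4095) 4095 else 65535
  }
  new("ImageStack", voxels = voxels, voxelSize = as.numeric(voxelSize),
      channelRoles = structure(as.integer(channelRoles),
                               names = names(channelRoles)),
      bitMax = as.numeric(bitMax))
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack:", d[1], "channel(s),",
      paste(d[2:4], collapse = " x "), "voxels (z y x)\n")
  cat("  voxel size (zyx, um):",
      paste(signif(object@voxelSize, 4), collapse = " x "), "\n")
  cat("  roles:", paste(names(object@channelRoles), object@channelRoles,
                        sep = "=", collapse = ", "), "\n")
  cat("  bitMax:", object@bitMax, "\n")
})

#' RoiMask: TH-defined region of interest with soma labels
#'
#' Binary region-of-interest volume derived from the TH immunolabel channel,
#' together with an integer soma labelling (0 = background, k = soma of cell
#' k) and per-cell soma volumes in cubic micrometres.
#'
#' @slot mask logical 3D array `[z, y, x]`: TH-positive region.
#' @slot somaLabels integer 3D array, same dimensions; soma voxels are a
#'   subset of the ROI.
#' @slot somaVolumes numeric, soma volume per cell (um^3).
#' @slot voxelSize numeric(3), micrometres per voxel (z, y, x).
#' @name RoiMask-class
#' @aliases RoiMask
#' @exportClass RoiMask
setClass("RoiMask",
  representation(
    mask = "array",
    somaLabels = "array",
    somaVolumes = "numeric",
    voxelSize = "numeric"
  )
)

setValidity("RoiMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a logical 3D array")
  if (!identical(dim(object@mask), dim(object@somaLabels)))
    msg <- c(msg, "somaLabels must match mask dimensions")
  if (any(object@somaLabels > 0 & !object@mask))
    msg <- c(msg, "soma voxels must lie inside the ROI")
  k <- max(object@somaLabels)
  if (length(object@somaVolumes) != k)
    msg <- c(msg, "somaVolumes length must equal the number of labels")
  if (k > 0) {
    counts <- tabulate(object@somaLabels[object@somaLabels > 0], nbins = k)
    expect <- counts * prod(object@voxelSize)
    if (any(abs(expect - object@somaVolumes) > 1e-8 * pmax(1, expect)))
      msg <- c(msg, "somaVolumes must equal label voxel counts x voxel volume")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RoiMask", function(object) {
  cat("RoiMask:", paste(dim(object@mask), collapse = " x "),
      "voxels;", sum(object@mask), "in ROI;",
      nCells(object), "soma(e)\n")
})

#' SegmentedObject: one 3D connected component
#'
#' A connected set of foreground voxels from one channel, carrying the voxel
#' coordinates (1-based array indices, z/y/x columns) and the intensities of
#' *all* channels at those voxels so that downstream colocalization can be
#' computed without re-reading the stack.
#'
#' @slot channel character(1), role of the channel the object was segmented
#'   from.
#' @slot coords integer matrix (n x 3), columns z, y, x.
#' @slot intensities numeric matrix (n x channels) with role column names.
#' @slot voxelSize numeric(3), micrometres per voxel (z, y, x).
#' @name SegmentedObject-class
#' @aliases SegmentedObject
#' @exportClass SegmentedObject
setClass("SegmentedObject",
  representation(
    channel = "character",
    coords = "matrix",
    intensities = "matrix",
    voxelSize = "numeric"
  )
)

setValidity("SegmentedObject", function(object) {
  msg <- character()
  if (nrow(object@coords) < 1L)
    msg <- c(msg, "object must be non-empty")
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns (z, y, x)")
  if (nrow(object@intensities) != nrow(object@coords))
    msg <- c(msg, "intensities must have one row per voxel")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentedObject", function(object) {
  cat("SegmentedObject (", object@channel, "): ", nrow(object@coords),
      " voxel(s), volume ", signif(objectVolume(object), 4), " um^3\n",
      sep = "")
})

#' BeamEventSeries: per-second beam positions for one fly
#'
#' Output of a multibeam activity monitor: the index (1-based) of the infrared
#' beam at the fly's position for each second of the recording, plus the
#' monitor geometry (number of beams and the span between the first and last
#' beam in millimetres).
#'
#' @slot tubeId character(1) identifier.
#' @slot beams integer vector, one entry per second, each in `[1, nBeams]`.
#' @slot nBeams integer(1), number of beams (default monitors have 17).
#' @slot spanMm numeric(1), distance first to last beam (mm).
#' @name BeamEventSeries-class
#' @aliases BeamEventSeries
#' @exportClass BeamEventSeries
setClass("BeamEventSeries",
  representation(
    tubeId = "character",
    beams = "integer",
    nBeams = "integer",
    spanMm = "numeric"
  )
)

setValidity("BeamEventSeries", function(object) {
  msg <- character()
  if (object@nBeams < 2L) msg <- c(msg, "nBeams must be >= 2")
  if (object@spanMm <= 0) msg <- c(msg, "spanMm must be > 0")
  if (length(object@beams) < 1L) msg <- c(msg, "series must be non-empty")
  if (any(object@beams < 1L | object@beams > object@nBeams))
    msg <- c(msg, "beam indices must lie in [1, nBeams]")
  if (length(msg)) msg else TRUE
})

#' Construct a BeamEventSeries
#'
#' @param beams integer vector of per-second beam indices (1-based).
#' @param tubeId identifier for the tube/fly.
#' @param nBeams number of beams in the monitor.
#' @param spanMm distance between first and last beam, mm.
#' @return A [BeamEventSeries-class] object.
#' @export
BeamEventSeries <- function(beams, tubeId = "tube1", nBeams = 17L,
                            spanMm = 51) {
  new("BeamEventSeries", tubeId = as.character(tubeId),
      beams = as.integer(beams), nBeams = as.integer(nBeams),
      spanMm = as.numeric(spanMm))
}

setMethod("show", "BeamEventSeries", function(object) {
  cat("BeamEventSeries", object@tubeId, ":", length(object@beams),
      "s,", object@nBeams, "beams over", object@spanMm, "mm\n")
})
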