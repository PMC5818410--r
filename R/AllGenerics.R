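#' Accessors for mitomorph containers
#'
#' @param x an [ImageStack-class], [RoiMask-class], [SegmentedObject-class] or
#'   [BeamEventSeries-class] object.
#' @param role optional channel role name; for `voxelData` selects one
#'   channel and returns a 3D array `[z, y, x]`.
#' @return `voxelData` returns a 3D (one role) or 4D numeric array;
#'   `voxelSize` a numeric(3) in micrometres (z, y, x); `channelRoles` the
#'   named role map; `bitMax` the saturation intensity; `nCells` the number of
#'   labelled somata; `somaVolumes` their volumes in um^3; `roiVolume` the ROI
#'   volume in um^3.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x, role = NULL) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("bitMax", function(x) standardGeneric("bitMax"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("somaVolumes", function(x) standardGeneric("somaVolumes"))

#' @rdname accessors
#' @export
setGeneric("roiVolume", function(x) standardGeneric("roiVolume"))

#' @rdname accessors
#' @export
setMethod("voxelData", "ImageStack", function(x, role = NULL) {
  if (is.null(role)) return(x@voxels)
  idx <- .roleIndex(x, role)
  arr <- x@voxels[idx, , , , drop = TRUE]
  dim(arr) <- dim(x@voxels)[2:4]
  arr
})

#' @rdname accessors
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "RoiMask", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "SegmentedObject", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("channelRoles", "ImageStack", function(x) x@channelRoles)

#' @rdname accessors
#' @export
setMethod("bitMax", "ImageStack", function(x) x@bitMax)

#' @rdname accessors
#' @export
setMethod("nCells", "RoiMask", function(x) as.integer(max(x@somaLabels)))

#' @rdname accessors
#' @export
setMethod("somaVolumes", "RoiMask", function(x) x@somaVolumes)

#' @rdname accessors
#' @export
setMethod("roiVolume", "RoiMask",
          function(x) sum(x@mask) * prod(x@voxelSize))

#' ROI membership mask
#'
#' @param x a [RoiMask-class].
#' @return Logical 3D array of the TH-positive region.
#' @export
roiMask <- function(x) {
  stopifnot(is(x, "RoiMask"))
  x@mask
}

#' Soma label volume
#'
#' @param x a [RoiMask-class].
#' @return Integer 3D array; 0 background, k = soma of cell k.
#' @export
somaLabels <- function(x) {
  stopifnot(is(x, "RoiMask"))
  x@somaLabels
}

#' SegmentedObject accessors
#'
#' @param obj a [SegmentedObject-class].
#' @return `objectCoords`: integer matrix of voxel indices (z, y, x);
#'   `objectIntensities`: per-voxel intensity matrix with role columns;
#'   `objectChannel`: the role the object was segmented from; `nVoxels`: the
#'   voxel count; `objectCentroid`: the mean voxel index (z, y, x).
#' @name object-accessors
#' @export
objectCoords <- function(obj) obj@coords

#' @rdname object-accessors
#' @export
objectIntensities <- function(obj) obj@intensities

#' @rdname object-accessors
#' @export
objectChannel <- function(obj) obj@channel

#' @rdname object-accessors
#' @export
nVoxels <- function(obj) nrow(obj@coords)

#' @rdname object-accessors
#' @export
objectCentroid <- function(obj) colMeans(obj@coords)

#' BeamEventSeries accessors
#'
#' @param x a [BeamEventSeries-class].
#' @return `beamIndices`: integer per-second beam indices; `beamSpacing`:
#'   distance between adjacent beams in mm, `spanMm / (nBeams - 1)`.
#' @name beam-accessors
#' @export
beamIndices <- function(x) x@beams

#' @rdname beam-accessors
#' @export
beamSpacing <- function(x) x@spanMm / (x@nBeams - 1)

# internal: resolve a role name to a channel index with a useful error
.roleIndex <- function(stack, role) {
  roles <- stack@channelRoles
  if (!role %in% names(roles))
    stop("channel role '", role, "' not present in stack (roles: ",
         paste(names(roles), collapse = ", "), ")")
  roles[[role]]
}
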