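#' Write an ImageStack to a multi-page TIFF with a metadata sidecar
#'
#' Pages are written channel-major (all z planes of channel 1, then channel 2,
#' ...), as 16-bit grayscale. Integer intensities up to 65535 round-trip
#' losslessly. Voxel size, channel roles, saturation level and page layout are
#' stored in a YAML sidecar at `<path>.yaml`, so channel identity never
#' depends on filename parsing.
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path.
#' @return Invisibly, the sidecar path.
#' @seealso [readStack]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@voxels
  if (max(v) > 65535)
    stop("intensities above 65535 cannot be stored as 16-bit TIFF")
  if (any(v != round(v)))
    stop("writeStack stores integer intensities; round the stack first")
  d <- dim(v)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ci in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      m <- matrix(v[ci, z, , ], nrow = d[3], ncol = d[4])
      pages[[k]] <- m / 65535
      k <- k + 1L
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "LZW"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF to '", path, "'")
  meta <- list(
    voxel_size_zyx = as.numeric(stack@voxelSize),
    channel_roles = as.list(stack@channelRoles),
    bit_max = stack@bitMax,
    n_channels = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
    page_order = "channel_major"
  )
  sidecar <- paste0(path, ".yaml")
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Read an ImageStack written by writeStack
#'
#' Metadata come from the YAML sidecar written alongside the TIFF. A
#' `channelMap` (named list/vector, role -> channel index) overrides or
#' replaces the sidecar's role map; every role it names must exist in the
#' file. If the sidecar is missing, `channelMap` is required and the voxel
#' size falls back to `defaultVoxelSize` with a warning.
#'
#' @param path TIFF path.
#' @param channelMap optional named role -> channel index map.
#' @param defaultVoxelSize voxel size used when no sidecar is present
#'   (z, y, x micrometres; the default keeps the study's 0.34 um z-step).
#' @return An [ImageStack-class].
#' @export
readStack <- function(path, channelMap = NULL,
                      defaultVoxelSize = c(0.34, 0.24, 0.24)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("page dimension mismatch across channels/planes")
  sidecar <- paste0(path, ".yaml")
  meta <- NULL
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  if (is.null(meta)) {
    if (is.null(channelMap))
      stop("no metadata sidecar found; supply channelMap")
    warning("no metadata sidecar for '", path, "': using default voxel size (",
            paste(defaultVoxelSize, collapse = ", "), ") um")
    nChan <- max(unlist(channelMap))
    if (length(pages) %% nChan != 0L)
      stop("page count ", length(pages), " is not a multiple of ", nChan,
           " channels")
    meta <- list(voxel_size_zyx = defaultVoxelSize,
                 channel_roles = as.list(channelMap),
                 bit_max = 65535,
                 n_channels = nChan, n_z = length(pages) %/% nChan)
  }
  roles <- meta$channel_roles
  if (!is.null(channelMap)) roles <- as.list(channelMap)
  nChan <- meta$n_channels
  nz <- meta$n_z
  for (r in names(roles)) {
    if (roles[[r]] < 1 || roles[[r]] > nChan)
      stop("channel role '", r, "' maps to channel ", roles[[r]],
           " but the file has only ", nChan, " channel(s)")
  }
  dd <- dims[[1]]
  vox <- array(0, c(nChan, nz, dd[1], dd[2]))
  k <- 1L
  for (ci in seq_len(nChan)) {
    for (z in seq_len(nz)) {
      vox[ci, z, , ] <- round(pages[[k]] * 65535)
      k <- k + 1L
    }
  }
  ImageStack(vox, voxelSize = as.numeric(meta$voxel_size_zyx),
             channelRoles = unlist(roles), bitMax = meta$bit_max)
}

#' Write beam-crossing series to CSV
#'
#' One row per (tube, second): columns `tube_id`, `second` (0-based,
#' contiguous), `beam_index` (1-based).
#'
#' @param seriesList list of [BeamEventSeries-class] objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeBeamTable <- function(seriesList, path) {
  if (is(seriesList, "BeamEventSeries")) seriesList <- list(seriesList)
  rows <- do.call(rbind, lapply(seriesList, function(s) {
    data.frame(tube_id = s@tubeId,
               second = seq_along(s@beams) - 1L,
               beam_index = s@beams)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read beam-crossing series from CSV
#'
#' @param path CSV with columns `tube_id`, `second`, `beam_index`.
#' @param nBeams number of beams in the monitor (17 for the study's monitor).
#' @param spanMm first-to-last beam distance in mm (51 for the study's
#'   monitor).
#' @return A list of [BeamEventSeries-class], one per tube. Seconds must be
#'   contiguous from 0 within each tube and beam indices within
#'   `[1, nBeams]`; violations are errors.
#' @export
readBeamTable <- function(path, nBeams = 17L, spanMm = 51) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tube_id", "second", "beam_index")
  if (!all(need %in% names(tab)))
    stop("beam table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$tube_id), function(tt) {
    tt <- tt[order(tt$second), ]
    if (!identical(as.integer(tt$second), seq_len(nrow(tt)) - 1L))
      stop("seconds for tube '", tt$tube_id[1],
           "' are not contiguous from 0")
    if (any(tt$beam_index < 1 | tt$beam_index > nBeams))
      stop("beam index out of range [1, ", nBeams, "] in tube '",
           tt$tube_id[1], "'")
    BeamEventSeries(tt$beam_index, tubeId = tt$tube_id[1],
                    nBeams = nBeams, spanMm = spanMm)
  })
  out[unique(tab$tube_id)]
}
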