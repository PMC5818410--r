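#' Specify a synthetic confocal z-stack
#'
#' Describes the acquisition geometry, the fluorescent objects, the TH-labelled
#' soma region, the optics (separable anisotropic Gaussian PSF) and the noise
#' model (Poisson shot noise followed by additive Gaussian read noise) of a
#' synthetic three-channel stack. Defaults mirror the study's acquisition: a
#' z-step of 0.34 um with an xy pixel size of 0.24 um (the lateral size is not
#' fixed by the optics description and is configurable), and an axial PSF
#' sigma derived from the 1.039 um optical section thickness
#' (sigma = FWHM / 2.355).
#'
#' @param shapeZyx integer(3), voxel counts along (z, y, x).
#' @param voxelSizeZyx numeric(3), micrometres per voxel (z, y, x).
#' @param shapes list of [shapes] (ShapeTruth) for the reporter channels.
#' @param thSomas list of ShapeTruth (normally [sphereShape] with
#'   `channel = "th"`) defining the TH-positive somata.
#' @param psfSigmaZyx numeric(3), Gaussian PSF sigma in micrometres per axis;
#'   zeros disable blurring.
#' @param poissonScale photon scale of the shot noise: intensities v are
#'   replaced by Poisson(v * scale) / scale; 0 disables shot noise.
#' @param gaussianSd additive read-noise standard deviation (intensity units);
#'   0 disables read noise.
#' @param redPuncta optional autophagosome-like red puncta placed by the
#'   generator: `list(n =, radius =, intensity =)`.
#' @param colocFraction fraction of `redPuncta` centred inside (at the centre
#'   of) green shapes; the rest are placed on signal-free background.
#' @param saturationTarget fraction of voxels that should sit at `bitMax`
#'   (overexposure); 0 keeps all voxels below saturation.
#' @param bitMax detector saturation level (default 4095, 12-bit).
#' @return A `StackSpec` list (validated).
#' @examples
#' spec <- stackSpec(shapeZyx = c(16, 32, 32),
#'                   shapes = list(sphereShape(c(2.5, 3.5, 3.5), 1.2)))
#' g <- generateStack(spec, seed = 7)
#' g$stack
#' @export
stackSpec <- function(shapeZyx,
                      voxelSizeZyx = c(0.34, 0.24, 0.24),
                      shapes = list(),
                      thSomas = list(),
                      psfSigmaZyx = c(0.44, 0.15, 0.15),
                      poissonScale = 1,
                      gaussianSd = 2,
                      redPuncta = NULL,
                      colocFraction = 0,
                      saturationTarget = 0,
                      bitMax = 4095) {
  stopifnot(length(shapeZyx) == 3, all(shapeZyx >= 1),
            length(voxelSizeZyx) == 3)
  if (any(voxelSizeZyx <= 0)) stop("voxel sizes must be > 0")
  if (colocFraction < 0 || colocFraction > 1)
    stop("colocFraction must lie in [0, 1]")
  if (saturationTarget < 0 || saturationTarget >= 1)
    stop("saturationTarget must lie in [0, 1)")
  spec <- list(shapeZyx = as.integer(shapeZyx),
               voxelSizeZyx = as.numeric(voxelSizeZyx),
               shapes = shapes, thSomas = thSomas,
               psfSigmaZyx = as.numeric(psfSigmaZyx),
               poissonScale = poissonScale, gaussianSd = gaussianSd,
               redPuncta = redPuncta, colocFraction = colocFraction,
               saturationTarget = saturationTarget, bitMax = bitMax)
  class(spec) <- "StackSpec"
  extent <- (spec$shapeZyx - 1) * spec$voxelSizeZyx
  for (s in c(shapes, thSomas)) .checkShapeInBounds(s, extent)
  spec
}

.shapeExtent <- function(s) {
  switch(s$kind,
         sphere = , punctum = rep(s$radius, 3),
         ellipsoid = s$semiAxes,
         tube = abs(s$axis) * s$length / 2 + s$radius,
         stop("unknown shape kind: ", s$kind))
}

.checkShapeInBounds <- function(s, extent) {
  half <- .shapeExtent(s)
  if (any(s$center - half < 0) || any(s$center + half > extent))
    stop("shape of kind '", s$kind, "' at (",
         paste(signif(s$center, 4), collapse = ", "),
         ") um extends outside the stack bounds")
  invisible(TRUE)
}

# rasterize one shape into a 3D array (adds intensity in place and returns)
.rasterizeShape <- function(arr, s, voxelSize) {
  d <- dim(arr)
  cz <- (seq_len(d[1]) - 1) * voxelSize[1]
  cy <- (seq_len(d[2]) - 1) * voxelSize[2]
  cx <- (seq_len(d[3]) - 1) * voxelSize[3]
  half <- .shapeExtent(s)
  iz <- which(cz >= s$center[1] - half[1] & cz <= s$center[1] + half[1])
  iy <- which(cy >= s$center[2] - half[2] & cy <= s$center[2] + half[2])
  ix <- which(cx >= s$center[3] - half[3] & cx <= s$center[3] + half[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(arr)
  if (s$kind %in% c("sphere", "punctum", "ellipsoid")) {
    ax <- if (s$kind == "ellipsoid") s$semiAxes else rep(s$radius, 3)
    qz <- ((cz[iz] - s$center[1]) / ax[1])^2
    qy <- ((cy[iy] - s$center[2]) / ax[2])^2
    qx <- ((cx[ix] - s$center[3]) / ax[3])^2
    inside <- outer(outer(qz, qy, `+`), qx, `+`) <= 1
  } else { # capsule
    u <- s$axis
    A <- s$center - u * s$length / 2
    dz <- cz[iz] - A[1]; dy <- cy[iy] - A[2]; dx <- cx[ix] - A[3]
    nzi <- length(iz); nyi <- length(iy); nxi <- length(ix)
    Dz <- array(dz, c(nzi, nyi, nxi))
    Dy <- array(rep(dy, each = nzi), c(nzi, nyi, nxi))
    Dx <- array(rep(dx, each = nzi * nyi), c(nzi, nyi, nxi))
    tpar <- Dz * u[1] + Dy * u[2] + Dx * u[3]
    tpar <- pmin(pmax(tpar, 0), s$length)
    dist2 <- Dz^2 + Dy^2 + Dx^2 - tpar * (2 * (Dz * u[1] + Dy * u[2] + Dx * u[3]) - tpar)
    inside <- dist2 <= s$radius^2
  }
  sub <- arr[iz, iy, ix, drop = FALSE]
  sub[inside] <- sub[inside] + s$intensity
  arr[iz, iy, ix] <- sub
  arr
}

.blur3d <- function(arr, sigmaVox) {
  if (all(sigmaVox <= 0)) return(arr)
  out <- .cpp_gaussian_blur(as.numeric(arr), dim(arr), as.numeric(sigmaVox))
  array(out, dim(arr))
}

#' Generate a synthetic three-channel z-stack with analytic ground truth
#'
#' Rasterizes every shape at its intensity (voxel centres inside the analytic
#' surface), convolves each channel with the anisotropic Gaussian PSF, applies
#' Poisson shot noise then Gaussian read noise, rounds to integer detector
#' counts and clips to `[0, bitMax]`. When `saturationTarget > 0` the stack is
#' rescaled so that approximately that fraction of voxels saturates. Channel
#' roles are fixed as `th = 1`, `mito_green = 2`, `red_reporter = 3`.
#'
#' @param spec a [stackSpec].
#' @param seed integer seed; identical spec + seed gives an identical stack.
#' @return list with `stack` (an [ImageStack-class]), `shapes` (the ShapeTruth
#'   list including generator-placed red puncta, each punctum carrying an
#'   `isColoc` flag), and `truth` (the analytic truth table from
#'   [shapeTruthTable] with an `isColoc` column).
#' @export
generateStack <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "StackSpec"))
  withr::with_seed(as.integer(seed), .generateStackImpl(spec))
}

.generateStackImpl <- function(spec) {
  d <- spec$shapeZyx
  vs <- spec$voxelSizeZyx
  extent <- (d - 1) * vs
  shapes <- spec$shapes

  # generator-placed red puncta: colocalized ones at green shape centres,
  # the others on background kept clear of any green signal
  greenShapes <- Filter(function(s) s$channel == "mito_green", shapes)
  if (!is.null(spec$redPuncta) && spec$redPuncta$n > 0) {
    rp <- spec$redPuncta
    nColoc <- round(spec$colocFraction * rp$n)
    if (nColoc > length(greenShapes))
      stop("more colocalized puncta than green host objects: ",
           "each colocalized punctum needs its own green shape")
    for (i in seq_len(rp$n)) {
      if (i <= nColoc) {
        host <- greenShapes[[i]]
        ctr <- host$center
      } else {
        ctr <- .sampleClearPoint(greenShapes, extent, rp$radius,
                                 clearance = 3 * max(spec$psfSigmaZyx))
      }
      p <- punctumShape(ctr, radius = rp$radius, intensity = rp$intensity)
      p$isColoc <- i <= nColoc
      shapes <- c(shapes, list(p))
    }
  }

  roles <- c(th = 1L, mito_green = 2L, red_reporter = 3L)
  vox <- array(0, c(3, d))
  chan <- list(array(0, d), array(0, d), array(0, d))
  for (s in spec$thSomas) chan[[1]] <- .rasterizeShape(chan[[1]], s, vs)
  for (s in shapes) {
    ci <- roles[[s$channel]]
    chan[[ci]] <- .rasterizeShape(chan[[ci]], s, vs)
  }

  sigmaVox <- spec$psfSigmaZyx / vs
  for (ci in 1:3) {
    a <- .blur3d(chan[[ci]], sigmaVox)
    if (spec$poissonScale > 0)
      a <- array(rpois(length(a), pmax(a, 0) * spec$poissonScale) /
                   spec$poissonScale, d)
    if (spec$gaussianSd > 0)
      a <- a + array(rnorm(length(a), 0, spec$gaussianSd), d)
    chan[[ci]] <- pmax(a, 0)
  }

  bitMax <- spec$bitMax
  if (spec$saturationTarget > 0) {
    all3 <- c(chan[[1]], chan[[2]], chan[[3]])
    q <- quantile(all3, 1 - spec$saturationTarget, names = FALSE)
    if (q <= 0) stop("saturationTarget exceeds the fraction of non-zero voxels")
    sc <- bitMax / q
    for (ci in 1:3) chan[[ci]] <- chan[[ci]] * sc
  }
  for (ci in 1:3) vox[ci, , , ] <- pmin(round(chan[[ci]]), bitMax)

  stack <- ImageStack(vox, voxelSize = vs, channelRoles = roles,
                      bitMax = bitMax)
  truth <- shapeTruthTable(shapes)
  if (!is.null(truth))
    truth$isColoc <- vapply(shapes, function(s) isTRUE(s$isColoc), logical(1))
  list(stack = stack, shapes = shapes, truth = truth)
}

# rejection-sample a punctum centre at least `clearance` um away from every
# green shape surface (approximated by its bounding ellipsoid radius)
.sampleClearPoint <- function(greenShapes, extent, radius, clearance,
                              maxTries = 200L) {
  for (i in seq_len(maxTries)) {
    ctr <- runif(3, min = radius, max = extent - radius)
    ok <- TRUE
    for (g in greenShapes) {
      rG <- max(.shapeExtent(g))
      if (sqrt(sum((ctr - g$center)^2)) < rG + radius + clearance) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(ctr)
  }
  stop("could not place a background punctum clear of green signal; ",
       "stack too crowded")
}
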