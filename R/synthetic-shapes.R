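#' Analytic ground-truth shapes for the synthetic stack generator
#'
#' Shapes are axis-aligned primitives with closed-form volume, surface area
#' and maximum diameter, so that the morphometric truth (including the
#' inverse sphericity 6V/DS) is known exactly and voxel-based measurements
#' can be validated against it.
#'
#' Surface areas: spheres and spheroids (two equal semi-axes) use the exact
#' closed forms; triaxial ellipsoids use the Thomsen approximation
#' (p = 1.6075, error below about 1.1%). Capsules (cylinders with
#' hemispherical caps) are exact.
#'
#' @param center numeric(3), shape centre in micrometres (z, y, x), measured
#'   from the centre of the first voxel.
#' @param radius radius in micrometres.
#' @param semiAxes numeric(3), ellipsoid semi-axes (z, y, x) in micrometres.
#' @param length cylindrical length of a capsule (caps excluded), um.
#' @param axis numeric(3), capsule axis direction (z, y, x); normalized
#'   internally.
#' @param intensity emitted intensity (arbitrary units) added to the channel.
#' @param channel channel role the shape fluoresces in.
#' @return A `ShapeTruth` list with elements `kind`, `center`, `channel`,
#'   `intensity`, geometric parameters and `trueVolume` (um^3), `trueSurface`
#'   (um^2), `trueDiameter` (um), `trueInvSphericity`.
#' @examples
#' s <- sphereShape(c(5, 5, 5), radius = 2)
#' s$trueInvSphericity  # exactly 1 for a sphere
#' e <- ellipsoidShape(c(5, 5, 5), semiAxes = c(1, 1, 4))
#' e$trueInvSphericity  # < 1: elongated
#' @name shapes
NULL

.shapeTruth <- function(kind, center, channel, intensity, params, V, S, D) {
  structure(c(list(kind = kind, center = as.numeric(center),
                   channel = channel, intensity = intensity),
              params,
              list(trueVolume = V, trueSurface = S, trueDiameter = D,
                   trueInvSphericity = 6 * V / (D * S))),
            class = "ShapeTruth")
}

#' @rdname shapes
#' @export
sphereShape <- function(center, radius, intensity = 100,
                        channel = "mito_green") {
  stopifnot(radius > 0)
  .shapeTruth("sphere", center, channel, intensity,
              list(radius = radius),
              V = 4 / 3 * pi * radius^3,
              S = 4 * pi * radius^2,
              D = 2 * radius)
}

#' @rdname shapes
#' @export
punctumShape <- function(center, radius = 0.4, intensity = 150,
                         channel = "red_reporter") {
  s <- sphereShape(center, radius, intensity, channel)
  s$kind <- "punctum"
  s
}

# exact spheroid / Thomsen triaxial ellipsoid surface area
.ellipsoidSurface <- function(semiAxes) {
  ax <- sort(as.numeric(semiAxes), decreasing = TRUE)
  a <- ax[1]; b <- ax[2]; c <- ax[3]
  tol <- 1e-12
  if (abs(a - c) < tol * a) return(4 * pi * a^2)
  if (abs(b - c) < tol * a) {            # prolate: a > b = c
    e <- sqrt(1 - (b / a)^2)
    return(2 * pi * b^2 * (1 + a / (b * e) * asin(e)))
  }
  if (abs(a - b) < tol * a) {            # oblate: a = b > c
    e <- sqrt(1 - (c / a)^2)
    return(2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e)))
  }
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' @rdname shapes
#' @export
ellipsoidShape <- function(center, semiAxes, intensity = 100,
                           channel = "mito_green") {
  semiAxes <- as.numeric(semiAxes)
  stopifnot(length(semiAxes) == 3, all(semiAxes > 0))
  .shapeTruth("ellipsoid", center, channel, intensity,
              list(semiAxes = semiAxes),
              V = 4 / 3 * pi * prod(semiAxes),
              S = .ellipsoidSurface(semiAxes),
              D = 2 * max(semiAxes))
}

#' @rdname shapes
#' @export
capsuleShape <- function(center, radius, length, axis = c(0, 0, 1),
                         intensity = 100, channel = "mito_green") {
  stopifnot(radius > 0, length >= 0)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  .shapeTruth("tube", center, channel, intensity,
              list(radius = radius, length = length, axis = axis),
              V = pi * radius^2 * length + 4 / 3 * pi * radius^3,
              S = 2 * pi * radius * length + 4 * pi * radius^2,
              D = length + 2 * radius)
}

#' Tabulate the analytic truth of a list of shapes
#'
#' @param shapes list of `ShapeTruth` objects.
#' @return data.frame with one row per shape: kind, channel, trueVolume,
#'   trueSurface, trueDiameter, trueInvSphericity.
#' @export
shapeTruthTable <- function(shapes) {
  do.call(rbind, lapply(shapes, function(s) {
    data.frame(kind = s$kind, channel = s$channel,
               trueVolume = s$trueVolume, trueSurface = s$trueSurface,
               trueDiameter = s$trueDiameter,
               trueInvSphericity = s$trueInvSphericity)
  }))
}
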