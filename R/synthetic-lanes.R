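#' Specify a synthetic western-blot lane table
#'
#' Emulates one blot: per-lane protein loading, the true uncleaved/cleaved
#' atg8a signal fractions, and multiplicative measurement noise. Total-protein
#' signal is proportional to loading; each band signal is proportional to
#' loading times its biological fraction.
#'
#' @param trueLoading numeric, relative protein loaded per lane (> 0).
#' @param bandFractions matrix or data.frame with columns `uncleaved` and
#'   `cleaved` (one row per lane), the true biological signal fractions
#'   (>= 0); defaults to 0.75/0.25 everywhere (same biology in every lane).
#' @param noiseSd relative (multiplicative) noise standard deviation; 0 gives
#'   exact proportionality.
#' @param genotype,collectionDay,replicateId optional per-lane annotations
#'   carried into the table.
#' @return A `LaneSpec` list.
#' @export
laneSpec <- function(trueLoading, bandFractions = NULL, noiseSd = 0,
                     genotype = NULL, collectionDay = NULL,
                     replicateId = NULL) {
  if (any(trueLoading <= 0)) stop("trueLoading must be > 0")
  n <- length(trueLoading)
  if (is.null(bandFractions))
    bandFractions <- data.frame(uncleaved = rep(0.75, n),
                                cleaved = rep(0.25, n))
  bandFractions <- as.data.frame(bandFractions)
  if (any(bandFractions < 0)) stop("band fractions must be >= 0")
  stopifnot(nrow(bandFractions) == n)
  structure(list(trueLoading = trueLoading, bandFractions = bandFractions,
                 noiseSd = noiseSd,
                 genotype = genotype %||% rep("control", n),
                 collectionDay = collectionDay %||% rep(1L, n),
                 replicateId = replicateId %||% seq_len(n)),
            class = "LaneSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a western-blot lane table with ground truth
#'
#' @param spec a [laneSpec].
#' @param seed integer seed for the measurement noise.
#' @return list with `lanes` (a data.frame ready for [normalizeLaneTable])
#'   and `truth` (the loading and band fractions used).
#' @export
generateLaneTable <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "LaneSpec"))
  n <- length(spec$trueLoading)
  withr::with_seed(as.integer(seed), {
    jig <- function(mu) mu * (1 + rnorm(length(mu), 0, spec$noiseSd))
    total <- jig(spec$trueLoading * 1000)
    b14 <- jig(spec$trueLoading * spec$bandFractions$uncleaved * 500)
    b12 <- jig(spec$trueLoading * spec$bandFractions$cleaved * 500)
    lanes <- data.frame(
      lane_id = seq_len(n),
      genotype = spec$genotype,
      collection_day = spec$collectionDay,
      replicate_id = spec$replicateId,
      total_protein_signal = pmax(total, 0),
      band_14kDa_signal = pmax(b14, 0),
      band_12kDa_signal = pmax(b12, 0))
    list(lanes = lanes,
         truth = data.frame(lane_id = seq_len(n),
                            trueLoading = spec$trueLoading,
                            uncleaved = spec$bandFractions$uncleaved,
                            cleaved = spec$bandFractions$cleaved))
  })
}
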