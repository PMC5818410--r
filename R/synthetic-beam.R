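#' Specify a synthetic beam-break recording
#'
#' Fly motion is a first-order Markov walk over beam indices at 1 Hz: each
#' second the fly moves up one beam, down one beam, or stays, with the given
#' probabilities (clamped at the tube ends). Defaults mirror the study's
#' monitor: 20 min at 1 Hz, 17 beams spanning 51 mm.
#'
#' @param durationS recording length in seconds (default 1200 = 20 min).
#' @param nBeams number of beams (default 17).
#' @param spanMm first-to-last beam distance (default 51 mm).
#' @param moveModel either `list(pUp =, pDown =, pStay =, pSlip =)` (the
#'   first three summing to 1; `pSlip` is an optional per-second probability
#'   of slipping back to the tube bottom, as flies losing grip do, and is
#'   applied before the step) or a preset: `"stay"` (immobile),
#'   `"monotone_up"` (climbs one beam per second from the bottom, then rests
#'   at the top), `"climber"` (pUp 0.30, pDown 0.05, pStay 0.65, pSlip 0.008:
#'   repeatedly climbs to the top and occasionally falls) or `"nonclimber"`
#'   (pUp 0.02, pDown 0.02, pStay 0.96: barely moves).
#' @param startBeam starting beam index.
#' @return A `BeamSpec` list.
#' @export
beamSpec <- function(durationS = 1200L, nBeams = 17L, spanMm = 51,
                     moveModel = "nonclimber", startBeam = 1L) {
  if (nBeams < 2) stop("nBeams must be >= 2")
  if (spanMm <= 0) stop("spanMm must be > 0")
  if (is.character(moveModel)) {
    moveModel <- switch(moveModel,
      stay = list(pUp = 0, pDown = 0, pStay = 1),
      monotone_up = "monotone_up",
      climber = list(pUp = 0.30, pDown = 0.05, pStay = 0.65, pSlip = 0.008),
      nonclimber = list(pUp = 0.02, pDown = 0.02, pStay = 0.96),
      stop("unknown move model preset: ", moveModel))
  }
  if (is.list(moveModel)) {
    if (is.null(moveModel$pSlip)) moveModel$pSlip <- 0
    ps <- unlist(moveModel[c("pUp", "pDown", "pStay")])
    if (any(ps < 0) || moveModel$pSlip < 0 || abs(sum(ps) - 1) > 1e-9)
      stop("move probabilities must be non-negative and sum to 1")
  }
  structure(list(durationS = as.integer(durationS),
                 nBeams = as.integer(nBeams), spanMm = spanMm,
                 moveModel = moveModel, startBeam = as.integer(startBeam)),
            class = "BeamSpec")
}

# climb totals computed directly from per-second displacements (independent
# of the extraction in extractClimbs): total = sum of positive displacements,
# climbs = number of maximal ascending runs
.traceTruth <- function(positions) {
  d <- diff(positions)
  tot <- sum(pmax(d, 0))
  # count ascending runs: an up-step starts a new climb if the previous
  # non-flat step was a down-step (or there was none)
  lastDir <- 0
  n <- 0L
  for (dd in d) {
    if (dd > 0 && lastDir <= 0) n <- n + 1L
    if (dd != 0) lastDir <- sign(dd)
  }
  data.frame(totalHeight = tot, nClimbs = n,
             averageHeight = if (n > 0) tot / n else 0,
             zeroClimbs = n == 0L)
}

#' Generate a beam-break series with its true climb summary
#'
#' @param spec a [beamSpec].
#' @param seed integer seed (same spec + seed reproduces the series).
#' @param tubeId identifier stored in the series.
#' @return list with `series` (a [BeamEventSeries-class]) and `truth` (the
#'   climb summary of the latent trace, computed from per-second
#'   displacements).
#' @export
generateBeamSeries <- function(spec, seed = 1L, tubeId = "tube1") {
  stopifnot(inherits(spec, "BeamSpec"))
  beams <- withr::with_seed(as.integer(seed), {
    b <- integer(spec$durationS)
    b[1] <- spec$startBeam
    if (identical(spec$moveModel, "monotone_up")) {
      for (t in seq_len(spec$durationS - 1))
        b[t + 1] <- min(b[t] + 1L, spec$nBeams)
    } else {
      mm <- spec$moveModel
      mv <- sample(c(1L, -1L, 0L), spec$durationS - 1, replace = TRUE,
                   prob = c(mm$pUp, mm$pDown, mm$pStay))
      slip <- runif(spec$durationS - 1) < mm$pSlip
      for (t in seq_len(spec$durationS - 1))
        b[t + 1] <- if (slip[t]) 1L else
          min(max(b[t] + mv[t], 1L), spec$nBeams)
    }
    b
  })
  series <- BeamEventSeries(beams, tubeId = tubeId, nBeams = spec$nBeams,
                            spanMm = spec$spanMm)
  list(series = series, truth = .traceTruth(buildTrace(series)))
}

#' Generate a labelled cohort of climbing and non-climbing flies
#'
#' @param nClimbers,nNonClimbers number of flies per class.
#' @param seed integer seed.
#' @param durationS recording length (seconds).
#' @return list with `series` (list of [BeamEventSeries-class]), `labels`
#'   (logical, TRUE = climber by construction) and `truth` (per-fly climb
#'   summaries of the latent traces).
#' @export
generateBeamCohort <- function(nClimbers, nNonClimbers, seed = 1L,
                               durationS = 1200L) {
  n <- nClimbers + nNonClimbers
  labels <- rep(c(TRUE, FALSE), c(nClimbers, nNonClimbers))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- beamSpec(durationS = durationS,
                     moveModel = if (labels[i]) "climber" else "nonclimber")
    out[[i]] <- generateBeamSeries(spec, seed = seed + i,
                                   tubeId = sprintf("tube%02d", i))
  }
  list(series = lapply(out, `[[`, "series"),
       labels = labels,
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}
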