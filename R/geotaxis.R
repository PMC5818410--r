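#' Convert a beam series to a position trace
#'
#' Position at second t is `(beamIndex(t) - 1) * spacing` with
#' `spacing = spanMm / (nBeams - 1)`; the study's monitor has 17 beams over
#' 51 mm, so beam 1 maps to 0 mm, beam 17 to 51 mm and the spacing is
#' 3.1875 mm.
#'
#' @param series a [BeamEventSeries-class].
#' @return Numeric vector of per-second positions (mm) with attributes
#'   `spanMm` and `spacing`.
#' @export
buildTrace <- function(series) {
  stopifnot(is(series, "BeamEventSeries"))
  sp <- beamSpacing(series)
  structure((series@beams - 1) * sp, spanMm = series@spanMm, spacing = sp)
}

#' Extract individual climbs from a position trace
#'
#' A climb is a maximal non-decreasing run of the trace with positive net
#' ascent: flat seconds extend a climb, any downward move ends it, and the
#' climb height is the difference between the run's end and start positions.
#'
#' @param trace numeric per-second positions (mm), length >= 2.
#' @return Numeric vector of climb heights (mm); empty if the fly never
#'   ascends.
#' @examples
#' extractClimbs(c(0, 3.1875, 9.5625, 6.375, 6.375, 12.75))
#' # 9.5625 6.3750
#' @export
extractClimbs <- function(trace) {
  stopifnot(length(trace) >= 2)
  d <- diff(trace)
  seg <- cumsum(c(0, d < 0))[-length(trace)]  # segment id per step
  up <- tapply(pmax(d, 0), seg, sum)
  as.numeric(up[up > 0])
}

#' Summarize climbing activity
#'
#' Total height climbed over the recording, number of climbs, and average
#' height (total / n, 0 when there are no climbs).
#'
#' @param climbs numeric climb heights from [extractClimbs].
#' @return data.frame with `totalHeight` (mm), `nClimbs`, `averageHeight`
#'   (mm), `zeroClimbs` (flag).
#' @export
climbSummary <- function(climbs) {
  n <- length(climbs)
  tot <- if (n) sum(climbs) else 0
  data.frame(totalHeight = tot, nClimbs = n,
             averageHeight = if (n) tot / n else 0,
             zeroClimbs = n == 0L)
}

#' ROC curve, AUC and Youden-optimal threshold
#'
#' Classifies `score >= threshold` as positive. The AUC is the pairwise
#' concordance fraction (ties count 1/2, i.e. the Mann-Whitney estimator);
#' the reported threshold maximizes Youden's J = sensitivity + specificity - 1,
#' with ties broken toward higher sensitivity (the lower threshold).
#'
#' @param scores numeric classifier scores (e.g. average height climbed).
#' @param labels logical or 0/1 true classes (TRUE = climber). Both classes
#'   must be present.
#' @return list of class `RocResult`: `auc`, `threshold`, `sensitivity`,
#'   `specificity` (at the threshold) and `curve` (a data.frame of all
#'   operating points).
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  # Mann-Whitney / concordance AUC with ties counting 1/2
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # thresholds ascending: first = highest sens
  out <- list(auc = auc, threshold = thr[best],
              sensitivity = sens[best], specificity = spec[best],
              curve = data.frame(threshold = thr, sensitivity = sens,
                                 specificity = spec, youdenJ = j))
  class(out) <- "RocResult"
  out
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; threshold = %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Classify climbers by average height
#'
#' @param summaries data.frame with an `averageHeight` column (from
#'   [climbSummary] rows) or a numeric vector of scores.
#' @param threshold classification threshold (a fly with
#'   `averageHeight >= threshold` is a climber).
#' @return Logical vector `isClimber`.
#' @export
classifyClimbers <- function(summaries, threshold) {
  scores <- if (is.data.frame(summaries)) summaries$averageHeight else summaries
  scores >= threshold
}
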