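#' Lane normalization factors
#'
#' REVERT-style normalization: each lane's signal divided by the maximum lane
#' signal on the same blot, so the brightest lane has factor 1 and every
#' factor lies in (0, 1]. The same rule applies to band signals (each band
#' divided by the most intense band of that size across lanes).
#'
#' @param signals numeric lane (or band) signals, >= 0 with at least one > 0.
#' @return Numeric LNFs.
#' @examples
#' laneNormalizationFactors(c(100, 50, 25))  # 1.0 0.5 0.25
#' @export
laneNormalizationFactors <- function(signals) {
  stopifnot(all(signals >= 0))
  m <- max(signals)
  if (m == 0) stop("all signals are zero: cannot normalize")
  signals / m
}

#' Normalize band signals by total-protein loading
#'
#' The band LNF is divided by the total-protein LNF of the same lane, removing
#' loading differences.
#'
#' @param bandLNF numeric band LNFs.
#' @param totalProteinLNF matching total-protein LNFs (> 0).
#' @return Normalized band signals.
#' @export
normalizeBands <- function(bandLNF, totalProteinLNF) {
  if (any(totalProteinLNF <= 0)) stop("total-protein LNF must be > 0")
  bandLNF / totalProteinLNF
}

#' Total and percent-cleaved atg8a
#'
#' Total atg8a is the sum of the normalized uncleaved (14 kDa) and cleaved
#' (12 kDa) signals; percent cleaved is `100 * cleaved / total`. Both-zero
#' input is undefined (`NA` values with attribute `undefined`).
#'
#' @param normalized14 normalized uncleaved (14 kDa) signal, >= 0.
#' @param normalized12 normalized cleaved (12 kDa) signal, >= 0.
#' @return list with `total` and `percentCleaved` (in percent, 0-100).
#' @export
atg8aSummary <- function(normalized14, normalized12) {
  stopifnot(all(normalized14 >= 0), all(normalized12 >= 0))
  total <- normalized14 + normalized12
  pct <- ifelse(total > 0, 100 * normalized12 / total, NA_real_)
  if (any(total == 0)) {
    warning("lane(s) with zero total atg8a: percent cleaved undefined")
    attr(pct, "undefined") <- TRUE
  }
  list(total = total, percentCleaved = pct)
}

#' Normalize a western-blot lane table
#'
#' Applies the full normalization to one blot: total-protein LNFs, per-band
#' LNFs, loading-corrected band signals, total atg8a and percent cleaved.
#' Band LNF denominators are computed within the blot only.
#'
#' @param laneTable data.frame with columns `lane_id`,
#'   `total_protein_signal`, `band_14kDa_signal`, `band_12kDa_signal` (extra
#'   columns such as genotype/collection day/replicate are carried through).
#' @return The table with added columns `total_protein_LNF`, `band_LNF_14`,
#'   `band_LNF_12`, `normalized_14`, `normalized_12`, `total_atg8a`,
#'   `percent_cleaved`.
#' @export
normalizeLaneTable <- function(laneTable) {
  need <- c("total_protein_signal", "band_14kDa_signal", "band_12kDa_signal")
  if (!all(need %in% names(laneTable)))
    stop("lane table must have columns: ", paste(need, collapse = ", "))
  out <- laneTable
  out$total_protein_LNF <- laneNormalizationFactors(out$total_protein_signal)
  out$band_LNF_14 <- laneNormalizationFactors(out$band_14kDa_signal)
  out$band_LNF_12 <- laneNormalizationFactors(out$band_12kDa_signal)
  out$normalized_14 <- normalizeBands(out$band_LNF_14, out$total_protein_LNF)
  out$normalized_12 <- normalizeBands(out$band_LNF_12, out$total_protein_LNF)
  s <- atg8aSummary(out$normalized_14, out$normalized_12)
  out$total_atg8a <- s$total
  out$percent_cleaved <- as.numeric(s$percentCleaved)
  out
}

#' Average technical replicates
#'
#' Arithmetic mean of normalized quantities per sample (replicates of the
#' same sample/collection day), applied after normalization.
#'
#' @param normalizedTable output of [normalizeLaneTable] across blots.
#' @param by character column names identifying a sample (e.g.
#'   `c("genotype", "collection_day")`).
#' @param measures columns to average.
#' @return data.frame of per-sample means.
#' @export
averageReplicates <- function(normalizedTable,
                              by = c("genotype", "collection_day"),
                              measures = c("total_atg8a",
                                           "percent_cleaved")) {
  stopifnot(all(by %in% names(normalizedTable)),
            all(measures %in% names(normalizedTable)))
  f <- as.formula(paste("cbind(", paste(measures, collapse = ", "), ") ~",
                        paste(by, collapse = " + ")))
  aggregate(f, data = normalizedTable, FUN = mean)
}
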