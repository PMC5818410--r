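#' Tidy statistical report over an experiment's measurement table
#'
#' For every stratum (e.g. region) and every measure, runs the normality-gated
#' comparison of each group to the control ([normalityGateCompare]) and binds
#' the results into one tidy report: the statistics behind each figure panel
#' for a (synthetic) cohort. Clusters with undefined values (e.g. an undefined
#' red:green ratio) are dropped from that measure only.
#'
#' @param measured data.frame of per-cluster measurements (e.g. from
#'   [measureCohort]); must contain the group column, the stratification
#'   columns and the measure columns.
#' @param design list with `control` (control group label), `groupCol`
#'   (default "group"), `byCols` (stratification columns, default "region"),
#'   `measures` (character vector of measure columns).
#' @return data.frame with one row per (stratum, measure, comparison):
#'   stratification columns, `measure`, `comparison`, `test`, `statistic`,
#'   `p`, `pAdj`, `stars`, `significant` (pAdj < 0.05). Re-running on the same
#'   table gives an identical report.
#' @export
summarizeExperiment <- function(measured, design) {
  stopifnot(is.list(design), !is.null(design$control),
            !is.null(design$measures))
  groupCol <- design$groupCol %||% "group"
  byCols <- design$byCols %||% "region"
  missing <- setdiff(c(groupCol, byCols, design$measures), names(measured))
  if (length(missing))
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "))
  strata <- unique(measured[, byCols, drop = FALSE])
  out <- list()
  for (s in seq_len(nrow(strata))) {
    sel <- rep(TRUE, nrow(measured))
    for (bc in byCols) sel <- sel & measured[[bc]] == strata[s, bc]
    sub <- measured[sel, , drop = FALSE]
    for (m in design$measures) {
      ok <- is.finite(sub[[m]])
      res <- normalityGateCompare(sub[[m]][ok], sub[[groupCol]][ok],
                                  control = design$control)
      res <- cbind(strata[s, , drop = FALSE], measure = m, res,
                   row.names = NULL)
      out[[length(out) + 1L]] <- res
    }
  }
  rep <- do.call(rbind, out)
  rep$significant <- !is.na(rep$pAdj) & rep$pAdj < 0.05
  rownames(rep) <- NULL
  rep
}
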