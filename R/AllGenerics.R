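#' @rdname SubgroupAssignment-class
#' @param x a SubgroupAssignment or BalanceReport object.
#' @export
setGeneric("lowIds", function(x) standardGeneric("lowIds"))

#' @rdname SubgroupAssignment-class
#' @export
setGeneric("highIds", function(x) standardGeneric("highIds"))

#' @rdname KMCurve-class
#' @param x a KMCurve object.
#' @export
setGeneric("survMedian", function(x) standardGeneric("survMedian"))

#' @rdname ScreenResult-class
#' @param x a ScreenResult object.
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname BalanceReport-class
#' @param x a BalanceReport object.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

setMethod("lowIds", "SubgroupAssignment", function(x) x@lowIds)
setMethod("highIds", "SubgroupAssignment", function(x) x@highIds)
setMethod("lowIds", "BalanceReport", function(x) x@lowIds)
setMethod("highIds", "BalanceReport", function(x) x@highIds)
setMethod("survMedian", "KMCurve", function(x) x@median)
setMethod("screenTable", "ScreenResult", function(x) x@table)
setMethod("converged", "BalanceReport", function(x) x@converged)

setMethod("show", "SubgroupAssignment", function(object) {
  nMid <- sum(!names(object@scaled) %in% c(object@lowIds, object@highIds))
  cat("SubgroupAssignment for probe", object@probeId, "\n",
      sprintf(" low (<= %.2f): %d  high (>= %.2f): %d  mid: %d\n",
              object@lowThreshold, length(object@lowIds),
              object@highThreshold, length(object@highIds), nMid))
  if (length(object@flags)) cat(" flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "KMCurve", function(object) {
  cat("KMCurve:", object@n, "subjects,", sum(object@nEvent), "events,",
      length(object@censorTimes), "censored\n")
  med <- object@median
  cat(" median survival:", if (is.na(med)) "undefined (S(t) never reaches 0.5)"
      else format(med), "\n")
})

setMethod("show", "SurvivalTestResult", function(object) {
  cat(sprintf("%s test: statistic = %.4g, two-sided p = %.4g (n = %d vs %d)\n",
              object@testName, object@statistic, object@pValue,
              object@nPerGroup[1L], object@nPerGroup[2L]))
  if (length(object@flags)) cat(" flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BalanceReport", function(object) {
  cat("BalanceReport:", if (object@converged) "converged" else "NOT converged",
      "after", object@iterations, "iterations (alpha =", object@alpha, ")\n",
      sprintf(" groups: low %d (removed %d), high %d (removed %d)\n",
              length(object@lowIds), length(object@removedLow),
              length(object@highIds), length(object@removedHigh)))
  if (nrow(object@scanAfter))
    cat(" smallest covariate p after balancing:",
        format(min(object@scanAfter$p), digits = 4), "\n")
})

setMethod("show", "ScreenResult", function(object) {
  tab <- object@table
  cat("ScreenResult:", nrow(tab), "probes;",
      sum(tab$flag == "ok"), "tested,",
      sum(tab$flag != "ok"), "skipped\n",
      " test:", object@params$test,
      " thresholds:", object@params$lowThreshold, "/",
      object@params$highThreshold, "\n")
  ok <- tab[tab$flag == "ok", , drop = FALSE]
  if (nrow(ok)) {
    top <- ok[order(ok$p_os), , drop = FALSE][1L, ]
    cat(sprintf(" top probe: %s (p_os = %.3g)\n", top$probe_id, top$p_os))
  }
})

setMethod("show", "ModerationParams", function(object) {
  cat(sprintf("ModerationParams: d0 = %s, s0^2 = %.4g\n",
              if (is.infinite(object@d0)) "Inf" else format(object@d0, digits = 4),
              object@s0sq))
})

setMethod("show", "GSEAResult", function(object) {
  cat(sprintf("GSEAResult '%s': ES = %.3f, NES = %.3f, p_perm = %.4g (%d permutations)\n",
              object@setName, object@es, object@nes, object@pPerm,
              object@nPermutations))
  cat(" leading edge:", length(object@leadingEdge), "genes\n")
})

setMethod("show", "SyntheticCohortSpec", function(object) {
  cat("SyntheticCohortSpec:", object@nPatients, "patients x", object@nProbes,
      "probes\n",
      sprintf(" biomarker slope %.2f, module %d genes at log2FC %.2f\n",
              object@biomarkerBeta, object@moduleSize, object@moduleLog2fc),
      sprintf(" hazard: log HR %.2f per unit z, baseline %.3f/month, censor %.3f/month\n",
              object@hazardLogHr, object@baselineHazard, object@censorHazard),
      " seed:", object@seed, "\n")
})
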