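#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ScreenCohort: expression matrix plus clinical annotation
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"exprs"} assay
#' holds the log2 probe-by-sample intensity matrix and whose \code{colData}
#' carries per-patient survival endpoints (\code{os_time}/\code{os_event},
#' optionally \code{efs_time}/\code{efs_event}), demographics and the
#' categorical covariates (mutations, karyotype, FAB class) used for
#' subgroup balancing. Covariate column names are recorded in
#' \code{metadata(x)$covariates}.
#'
#' Validity requires unique probe and sample identifiers, finite non-missing
#' expression values (\code{NA} marks a masked/absent call), non-negative
#' survival times and 0/1 event flags.
#'
#' @aliases ScreenCohort-class
#' @exportClass ScreenCohort
setClass("ScreenCohort", contains = "SummarizedExperiment")

setValidity("ScreenCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (any(!is.finite(x) & !is.na(x)))
      msg <- c(msg, "expression values must be finite or NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate probe id '%s'",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate sample id '%s'",
                          colnames(object)[duplicated(colnames(object))][1L]))
  cd <- SummarizedExperiment::colData(object)
  for (col in c("os_time", "efs_time")) {
    if (col %in% colnames(cd)) {
      v <- cd[[col]]
      if (any(v < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("negative %s", col))
    }
  }
  for (col in c("os_event", "efs_event")) {
    if (col %in% colnames(cd)) {
      v <- cd[[col]]
      if (!all(v %in% c(0, 1) | is.na(v)))
        msg <- c(msg, sprintf("%s values must be 0 or 1", col))
    }
  }
  if (!"os_time" %in% colnames(cd) || !"os_event" %in% colnames(cd))
    msg <- c(msg, "colData must contain os_time and os_event")
  if (length(msg)) msg else TRUE
})

#' SubgroupAssignment: low/high expresser partition for one probe
#'
#' Result of min-max scaling one probe and cutting the scaled expression
#' range at the low/high thresholds. Samples strictly between the
#' thresholds are "mid" and excluded from both groups.
#'
#' @slot probeId probe identifier.
#' @slot scaled named numeric vector of scaled values in [0,1] (NA = missing).
#' @slot lowIds,highIds sample ids with scaled value \eqn{\le} low threshold /
#'   \eqn{\ge} high threshold.
#' @slot lowThreshold,highThreshold the range cut points (defaults 0.3/0.7).
#' @slot flags character; may contain \code{"underpowered"} when either group
#'   is below the configured minimum size.
#' @exportClass SubgroupAssignment
setClass("SubgroupAssignment",
  representation(probeId = "character", scaled = "numeric",
                 lowIds = "character", highIds = "character",
                 lowThreshold = "numeric", highThreshold = "numeric",
                 flags = "character"))

setValidity("SubgroupAssignment", function(object) {
  msg <- character()
  if (length(intersect(object@lowIds, object@highIds)))
    msg <- c(msg, "low and high groups overlap")
  lo <- object@lowThreshold; hi <- object@highThreshold
  if (!(lo >= 0 && lo < hi && hi <= 1))
    msg <- c(msg, "thresholds must satisfy 0 <= low < high <= 1")
  sc <- object@scaled
  if (any(sc < -1e-12 | sc > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "scaled values outside [0,1]")
  if (any(sc[object@lowIds] > lo + 1e-12, na.rm = TRUE))
    msg <- c(msg, "a low-group member exceeds the low threshold")
  if (any(sc[object@highIds] < hi - 1e-12, na.rm = TRUE))
    msg <- c(msg, "a high-group member is below the high threshold")
  if (length(msg)) msg else TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot time distinct event times, increasing.
#' @slot survival estimated S(t) at each event time, non-increasing from 1.
#' @slot nRisk number at risk just before each event time.
#' @slot nEvent number of deaths at each event time.
#' @slot censorTimes times of censored observations.
#' @slot median smallest time with S(t) <= 0.5, or NA when S never
#'   reaches 0.5 (median undefined).
#' @slot n number of subjects.
#' @exportClass KMCurve
setClass("KMCurve",
  representation(time = "numeric", survival = "numeric", nRisk = "integer",
                 nEvent = "integer", censorTimes = "numeric",
                 median = "numeric", n = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly increasing")
  if (any(diff(object@survival) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
    msg <- c(msg, "survival outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' SurvivalTestResult: two-group survival comparison
#'
#' @slot statistic test statistic (chi-square for log-rank/Gehan, rank-sum
#'   W for the Wilcoxon test).
#' @slot pValue two-sided p-value.
#' @slot testName one of "logrank", "ranksum", "gehan".
#' @slot nPerGroup integer vector (nA, nB).
#' @slot flags character; e.g. "degenerate" when the statistic is undefined.
#' @exportClass SurvivalTestResult
setClass("SurvivalTestResult",
  representation(statistic = "numeric", pValue = "numeric",
                 testName = "character", nPerGroup = "integer",
                 flags = "character"))

setValidity("SurvivalTestResult", function(object) {
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) "p-value outside [0,1]" else TRUE
})

#' BalanceReport: audit of the randomized covariate rebalancing
#'
#' @slot lowIds,highIds the retained, balanced subgroups.
#' @slot removedLow,removedHigh sample ids removed from each side.
#' @slot scanBefore,scanAfter per-covariate-level Fisher scans at entry and
#'   exit (columns covariate, level, countLow, countHigh, p).
#' @slot trail per-iteration audit: iteration, covariate, level, action
#'   ("remove" or "readmit"), sample, group, p at that iteration.
#' @slot iterations number of iterations performed.
#' @slot converged TRUE when every covariate-level p >= alpha at exit.
#' @slot seed,alpha the run parameters.
#' @exportClass BalanceReport
setClass("BalanceReport",
  representation(lowIds = "character", highIds = "character",
                 removedLow = "character", removedHigh = "character",
                 scanBefore = "data.frame", scanAfter = "data.frame",
                 trail = "data.frame", iterations = "integer",
                 converged = "logical", seed = "integer", alpha = "numeric"))

setValidity("BalanceReport", function(object) {
  msg <- character()
  if (length(intersect(object@removedLow, object@lowIds)) ||
      length(intersect(object@removedHigh, object@highIds)))
    msg <- c(msg, "removed samples still present in retained groups")
  if (object@converged && nrow(object@scanAfter) &&
      any(object@scanAfter$p < object@alpha - 1e-12))
    msg <- c(msg, "converged report contains p_after below alpha")
  if (length(msg)) msg else TRUE
})

#' ScreenResult: per-probe survival-screen statistics
#'
#' One row per input probe (including skipped probes, which carry a flag),
#' with subgroup sizes, OS/EFS test p-values, BH q-values, per-group median
#' survival and a direction label.
#'
#' @slot table data.frame of per-probe records.
#' @slot params list of screen parameters (thresholds, test, minGroup, alpha).
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(table = "data.frame", params = "list"))

setValidity("ScreenResult", function(object) {
  tab <- object@table
  need <- c("probe_id", "n_low", "n_high", "p_os", "flag")
  if (!all(need %in% colnames(tab)))
    return(sprintf("screen table lacks column(s): %s",
                   paste(setdiff(need, colnames(tab)), collapse = ", ")))
  ok <- is.na(tab$p_os) | (tab$p_os >= 0 & tab$p_os <= 1)
  if (!all(ok)) return("p_os outside [0,1]")
  TRUE
})

#' ModerationParams: empirical-Bayes variance prior
#'
#' Scaled-F hyperparameters shared across probes: prior degrees of freedom
#' \code{d0} (possibly infinite, meaning complete shrinkage) and prior
#' variance \code{s0sq}.
#'
#' @slot d0 prior degrees of freedom, positive (may be \code{Inf}).
#' @slot s0sq prior variance, positive.
#' @exportClass ModerationParams
setClass("ModerationParams",
  representation(d0 = "numeric", s0sq = "numeric"))

setValidity("ModerationParams", function(object) {
  msg <- character()
  if (!(object@d0 >= 0)) msg <- c(msg, "d0 must be non-negative")
  if (!(object@s0sq > 0)) msg <- c(msg, "s0sq must be positive")
  if (length(msg)) msg else TRUE
})

#' GSEAResult: enrichment score with phenotype-permutation null
#'
#' @slot setName gene-set name.
#' @slot es observed enrichment score in [-1, 1].
#' @slot nes es normalized by the mean |es| of same-sign permutations.
#' @slot pPerm permutation p-value, >= 1/(nPermutations+1).
#' @slot nPermutations number of label permutations.
#' @slot leadingEdge genes driving the score (hits at or before the peak).
#' @slot runningSum the running enrichment statistic along the ranking.
#' @slot seed RNG seed used for the permutations.
#' @exportClass GSEAResult
setClass("GSEAResult",
  representation(setName = "character", es = "numeric", nes = "numeric",
                 pPerm = "numeric", nPermutations = "integer",
                 leadingEdge = "character", runningSum = "numeric",
                 seed = "integer"))

setValidity("GSEAResult", function(object) {
  msg <- character()
  if (abs(object@es) > 1 + 1e-9) msg <- c(msg, "|es| must be <= 1")
  if (object@nPermutations > 0L &&
      object@pPerm < 1 / (object@nPermutations + 1) - 1e-12)
    msg <- c(msg, "pPerm below the permutation floor 1/(n_perm+1)")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohortSpec: generative parameterization of a test cohort
#'
#' Full description of a simulated AML-like cohort: a latent per-patient
#' level z ~ Uniform(0,1) drives one planted biomarker probe, a co-expressed
#' downstream module, proportional-hazards exponential survival, and binary
#' mutation-like covariates whose prevalence is confounded with z.
#'
#' @slot nPatients,nProbes cohort dimensions.
#' @slot biomarkerBeta expression slope (log2 units) of the biomarker on z.
#' @slot baselineSd residual expression noise sd (log2 units).
#' @slot hazardLogHr log hazard ratio per unit z.
#' @slot baselineHazard baseline event hazard per month.
#' @slot censorHazard censoring hazard per month.
#' @slot efsHazardFactor EFS baseline hazard multiplier (default 1.3).
#' @slot weibullShape Weibull shape of the event times (1 = exponential).
#' @slot moduleSize,moduleLog2fc size and expression slope of the planted
#'   co-expressed module.
#' @slot confounders data.frame(name, base_prevalence, prevalence_slope) of
#'   z-linked binary covariates.
#' @slot nCovariateLevels number of levels of the survival-neutral FAB-like
#'   factor.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticCohortSpec
setClass("SyntheticCohortSpec",
  representation(nPatients = "integer", nProbes = "integer",
                 biomarkerBeta = "numeric", baselineSd = "numeric",
                 hazardLogHr = "numeric", baselineHazard = "numeric",
                 censorHazard = "numeric", efsHazardFactor = "numeric",
                 weibullShape = "numeric", moduleSize = "integer",
                 moduleLog2fc = "numeric", confounders = "data.frame",
                 nCovariateLevels = "integer", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
  if (object@nProbes < 1L) msg <- c(msg, "nProbes must be >= 1")
  if (object@moduleSize < 0L || object@moduleSize + 1L > object@nProbes)
    msg <- c(msg, "moduleSize must fit within nProbes (plus the biomarker)")
  if (object@baselineSd <= 0) msg <- c(msg, "baselineSd must be positive")
  if (object@baselineHazard <= 0 || object@censorHazard <= 0)
    msg <- c(msg, "hazards must be positive")
  if (object@weibullShape <= 0) msg <- c(msg, "weibullShape must be positive")
  cf <- object@confounders
  if (nrow(cf) &&
      !all(c("name", "base_prevalence", "prevalence_slope") %in% colnames(cf)))
    msg <- c(msg, "confounders needs columns name, base_prevalence, prevalence_slope")
  if (length(msg)) msg else TRUE
})
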