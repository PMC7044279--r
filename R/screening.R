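#' Genome-wide survival screen over all probes
#'
#' For every probe in the cohort: min-max scale across patients, cut the
#' scaled range into low (<= lowThreshold) and high (>= highThreshold)
#' expresser subgroups, and compare the subgroups on overall survival and,
#' when present, event-free survival. The default comparison is the
#' Wilcoxon rank-sum test on observed survival times (censoring flags
#' ignored); the censoring-aware log-rank and Gehan-Wilcoxon tests are
#' selectable. Constant probes are flagged \code{"degenerate"} and probes
#' with an informative group below \code{minGroup} are flagged
#' \code{"underpowered"}; both are skipped but still emitted, so the output
#' has exactly one row per input probe. No multiple-testing correction is
#' applied to the screen's raw p-values (hits are called at raw p < alpha),
#' but BH-FDR q-values are reported in extra columns. The whole stage is
#' deterministic.
#'
#' @param cohort A \linkS4class{ScreenCohort}.
#' @param lowThreshold,highThreshold Range cut points (defaults 0.3/0.7).
#' @param minGroup Minimum group size (default 10).
#' @param test \code{"ranksum"} (default), \code{"logrank"} or \code{"gehan"}.
#' @param alpha Screen significance level, recorded in the parameters.
#' @return A \linkS4class{ScreenResult}.
#' @examples
#' sp <- SyntheticCohortSpec(nPatients = 60L, nProbes = 50L, seed = 7L)
#' res <- screenProbes(generateCohort(sp))
#' head(screenTable(res))
#' @export
screenProbes <- function(cohort, lowThreshold = 0.3, highThreshold = 0.7,
                         minGroup = 10L, test = c("ranksum", "logrank", "gehan"),
                         alpha = 0.05) {
  stopifnot(methods::is(cohort, "ScreenCohort"))
  test <- match.arg(test)
  x <- exprsMatrix(cohort)
  clin <- clinicalTable(cohort)
  hasEfs <- all(c("efs_time", "efs_event") %in% colnames(clin))
  probes <- rownames(x)
  emptyRec <- function(id, flag) data.frame(
    probe_id = id, n_low = NA_integer_, n_high = NA_integer_,
    p_os = NA_real_, p_efs = NA_real_,
    median_os_low = NA_real_, median_os_high = NA_real_,
    median_efs_low = NA_real_, median_efs_high = NA_real_,
    direction = NA_character_, flag = flag)
  recs <- lapply(probes, function(pid) {
    vals <- x[pid, ]
    sc <- tryCatch(scaleProbe(vals), degenerateProbe = function(e) NULL,
                   error = function(e) if (inherits(e, "degenerateProbe")) NULL else stop(e))
    if (is.null(sc)) return(emptyRec(pid, "degenerate"))
    asg <- assignSubgroups(sc, lowThreshold, highThreshold, minGroup, pid)
    if ("underpowered" %in% asg@flags) {
      rec <- emptyRec(pid, "underpowered")
      rec$n_low <- length(asg@lowIds); rec$n_high <- length(asg@highIds)
      return(rec)
    }
    lo <- asg@lowIds; hi <- asg@highIds
    iL <- match(lo, clin$sample_id); iH <- match(hi, clin$sample_id)
    pOs <- compareSurvival(clin, lo, hi, "os", test)@pValue
    kmOsL <- kmEstimate(clin$os_time[iL], clin$os_event[iL])
    kmOsH <- kmEstimate(clin$os_time[iH], clin$os_event[iH])
    pEfs <- NA_real_; medEfsL <- NA_real_; medEfsH <- NA_real_
    if (hasEfs) {
      pEfs <- compareSurvival(clin, lo, hi, "efs", test)@pValue
      medEfsL <- survMedian(kmEstimate(clin$efs_time[iL], clin$efs_event[iL]))
      medEfsH <- survMedian(kmEstimate(clin$efs_time[iH], clin$efs_event[iH]))
    }
    medL <- survMedian(kmOsL); medH <- survMedian(kmOsH)
    direction <- if (is.na(medL) || is.na(medH) || medL == medH) "mixed"
                 else if (medH < medL) "high_worse" else "low_worse"
    data.frame(probe_id = pid, n_low = length(lo), n_high = length(hi),
               p_os = pOs, p_efs = pEfs,
               median_os_low = medL, median_os_high = medH,
               median_efs_low = medEfsL, median_efs_high = medEfsH,
               direction = direction, flag = "ok")
  })
  tab <- do.call(rbind, recs)
  tab$q_os <- NA_real_; tab$q_efs <- NA_real_
  ok <- tab$flag == "ok"
  if (any(ok)) {
    tab$q_os[ok] <- bhAdjust(tab$p_os[ok])
    if (hasEfs) tab$q_efs[ok] <- bhAdjust(tab$p_efs[ok])
  } else {
    warning("no probe survived the degenerate/underpowered filters")
  }
  methods::new("ScreenResult", table = tab,
               params = list(lowThreshold = lowThreshold,
                             highThreshold = highThreshold,
                             minGroup = as.integer(minGroup),
                             test = test, alpha = alpha,
                             hasEfs = hasEfs))
}

#' Select and rank screen hits
#'
#' Hits are probes with p_os < alpha and, when \code{requireBoth} and EFS
#' was screened, p_efs < alpha as well; optionally intersected with a
#' user-supplied allowlist (the curated stand-in for literature-based
#' trimming of cancer-relevant genes). Hits are ranked by ascending p_os.
#'
#' @param result A \linkS4class{ScreenResult}.
#' @param alpha Significance level (defaults to the screen's).
#' @param requireBoth Require significance on both OS and EFS (default TRUE
#'   when EFS is present).
#' @param allowlist Optional character vector of permitted probe ids.
#' @return data.frame of hit records, ranked by p_os.
#' @export
selectHits <- function(result, alpha = NULL, requireBoth = NULL,
                       allowlist = NULL) {
  stopifnot(methods::is(result, "ScreenResult"))
  tab <- result@table
  alpha <- alpha %||% result@params$alpha
  requireBoth <- requireBoth %||% result@params$hasEfs
  keep <- tab$flag == "ok" & !is.na(tab$p_os) & tab$p_os < alpha
  if (requireBoth && result@params$hasEfs)
    keep <- keep & !is.na(tab$p_efs) & tab$p_efs < alpha
  if (!is.null(allowlist)) keep <- keep & tab$probe_id %in% allowlist
  hits <- tab[keep, , drop = FALSE]
  hits[order(hits$p_os), , drop = FALSE]
}

#' Write a ScreenResult as TSV plus a JSON run manifest
#'
#' @param result A \linkS4class{ScreenResult}.
#' @param path Output TSV path; the manifest is written next to it with
#'   extension \code{.manifest.json}.
#' @return \code{path}, invisibly.
#' @export
writeScreenResult <- function(result, path) {
  stopifnot(methods::is(result, "ScreenResult"))
  write.table(result@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(result@params, list(n_probes = nrow(result@table),
                          package = "SurvScreen",
                          version = as.character(utils::packageVersion("SurvScreen")))),
    sub("\\.tsv$", "", path) |> paste0(".manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
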