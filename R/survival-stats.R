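#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function under right censoring,
#' S(t) = prod over event times t_i <= t of (1 - d_i/n_i). Deaths are
#' processed before censorings tied at the same time (the standard
#' convention). The reported median is the smallest observed time with
#' S(t) <= 0.5; when the curve never reaches 0.5 the median is undefined
#' and reported as \code{NA}.
#'
#' @param time Non-negative survival times (months by package convention).
#' @param event 0/1 event flags (1 = death observed).
#' @return A \linkS4class{KMCurve}.
#' @examples
#' kmEstimate(c(1, 2, 3, 4, 5), c(1, 1, 1, 1, 1))
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("empty survival input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- as.integer(event[keep])
  n <- length(time)
  eventTimes <- sort(unique(time[event == 1L]))
  if (length(eventTimes)) {
    nRisk <- vapply(eventTimes, function(t) sum(time >= t), integer(1L))
    nEvent <- vapply(eventTimes, function(t) sum(time == t & event == 1L),
                     integer(1L))
    surv <- cumprod(1 - nEvent / nRisk)
  } else {
    nRisk <- integer(); nEvent <- integer(); surv <- numeric()
  }
  med <- if (any(surv <= 0.5 + 1e-12)) eventTimes[which(surv <= 0.5 + 1e-12)[1L]]
         else NA_real_
  methods::new("KMCurve", time = as.numeric(eventTimes), survival = surv,
               nRisk = nRisk, nEvent = nEvent,
               censorTimes = as.numeric(sort(time[event == 0L])),
               median = med, n = n)
}

#' KM curve as a plotting-ready data.frame
#'
#' @param km A \linkS4class{KMCurve}.
#' @return data.frame with columns time, survival, at_risk, events.
#' @export
kmFrame <- function(km) {
  stopifnot(methods::is(km, "KMCurve"))
  data.frame(time = km@time, survival = km@survival,
             at_risk = km@nRisk, events = km@nEvent)
}

## Shared weighted log-rank machinery. weightFn maps the number at risk
## n_i at each event time to the weight (1 for log-rank, n_i for Gehan).
weightedLogrank <- function(timeA, eventA, timeB, eventB, weightFn, testName) {
  if (!length(timeA) || !length(timeB)) stop("both groups must be non-empty")
  time <- c(timeA, timeB)
  event <- as.integer(c(eventA, eventB))
  grpA <- c(rep(TRUE, length(timeA)), rep(FALSE, length(timeB)))
  nPer <- c(length(timeA), length(timeB))
  if (!any(event == 1L))
    return(methods::new("SurvivalTestResult", statistic = NA_real_,
                        pValue = NA_real_, testName = testName,
                        nPerGroup = as.integer(nPer), flags = "degenerate"))
  eventTimes <- sort(unique(time[event == 1L]))
  U <- 0; V <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    ni <- sum(atRisk)
    n1i <- sum(atRisk & grpA)
    di <- sum(time == t & event == 1L)
    d1i <- sum(time == t & event == 1L & grpA)
    w <- weightFn(ni)
    U <- U + w * (d1i - di * n1i / ni)
    if (ni > 1L)
      V <- V + w^2 * di * (n1i / ni) * (1 - n1i / ni) * (ni - di) / (ni - 1)
  }
  if (V <= 0)
    return(methods::new("SurvivalTestResult", statistic = NA_real_,
                        pValue = NA_real_, testName = testName,
                        nPerGroup = as.integer(nPer), flags = "degenerate"))
  chisq <- U^2 / V
  methods::new("SurvivalTestResult", statistic = chisq,
               pValue = pchisq(chisq, df = 1, lower.tail = FALSE),
               testName = testName, nPerGroup = as.integer(nPer),
               flags = character())
}

#' Two-sided log-rank test
#'
#' Standard one-degree-of-freedom log-rank test: observed minus expected
#' events in group A accumulated over distinct event times, with the
#' hypergeometric variance at each time; the squared standardized statistic
#' is referred to chi-square(1).
#'
#' @param timeA,eventA Survival times and 0/1 event flags of group A.
#' @param timeB,eventB Same for group B.
#' @return A \linkS4class{SurvivalTestResult} (test name "logrank"). When
#'   neither group has any event the statistic is undefined and flagged
#'   "degenerate".
#' @examples
#' logrankTest(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  weightedLogrank(timeA, eventA, timeB, eventB, function(ni) 1, "logrank")
}

#' Gehan-Wilcoxon weighted log-rank test
#'
#' Weighted log-rank variant with weight n_i (the total number at risk) at
#' each event time, emphasizing early events; the censoring-aware analogue
#' of the rank-sum test.
#'
#' @inheritParams logrankTest
#' @return A \linkS4class{SurvivalTestResult} (test name "gehan").
#' @export
gehanWilcoxonTest <- function(timeA, eventA, timeB, eventB) {
  weightedLogrank(timeA, eventA, timeB, eventB, function(ni) ni, "gehan")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney test on raw values (the screen applies it to observed
#' survival times, ignoring censoring flags). The p-value is exact (from
#' the null rank-sum distribution) when the combined sample size is at most
#' \code{exactLimit} and there are no ties; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used, with
#' mid-ranks for ties.
#'
#' @param a,b Numeric samples.
#' @param exactLimit Combined-size bound for the exact p (default 12).
#' @return A \linkS4class{SurvivalTestResult} (test name "ranksum") whose
#'   statistic is the Mann-Whitney U of group \code{a}. When every value in
#'   both groups is identical, p = 1 with a "degenerate" flag.
#' @examples
#' ranksumTest(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
ranksumTest <- function(a, b, exactLimit = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  nA <- length(a); nB <- length(b)
  if (!nA || !nB) stop("both groups must be non-empty")
  nPer <- as.integer(c(nA, nB))
  pooled <- c(a, b)
  if (max(pooled) == min(pooled))
    return(methods::new("SurvivalTestResult", statistic = nA * nB / 2,
                        pValue = 1, testName = "ranksum", nPerGroup = nPer,
                        flags = "degenerate"))
  r <- rank(pooled)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && nA + nB <= exactLimit) {
    p <- if (U > nA * nB / 2)
      stats::pwilcox(U - 1, nA, nB, lower.tail = FALSE) + stats::pwilcox(nA * nB - U, nA, nB)
    else if (U < nA * nB / 2)
      stats::pwilcox(U, nA, nB) + stats::pwilcox(nA * nB - U - 1, nA, nB, lower.tail = FALSE)
    else 1
    p <- min(1, p)
  } else {
    n <- nA + nB
    tieTab <- table(pooled)
    sigma2 <- (nA * nB / 12) * ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    z <- U - nA * nB / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  }
  methods::new("SurvivalTestResult", statistic = U, pValue = p,
               testName = "ranksum", nPerGroup = nPer, flags = character())
}

#' Compare survival between two patient groups
#'
#' Convenience dispatcher used by the screen and the pipeline: runs the
#' requested test on a clinical table restricted to two sample-id sets.
#'
#' @param clinical Clinical data.frame (see \code{\link{readClinicalTable}}).
#' @param lowIds,highIds Sample-id character vectors.
#' @param endpoint \code{"os"} or \code{"efs"}.
#' @param test \code{"ranksum"} (observed times, censoring ignored),
#'   \code{"logrank"} or \code{"gehan"}.
#' @return A \linkS4class{SurvivalTestResult}.
#' @export
compareSurvival <- function(clinical, lowIds, highIds,
                            endpoint = c("os", "efs"),
                            test = c("ranksum", "logrank", "gehan")) {
  endpoint <- match.arg(endpoint)
  test <- match.arg(test)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% colnames(clinical)))
    stop(sprintf("endpoint '%s' not present in clinical table", endpoint))
  iL <- match(lowIds, clinical$sample_id)
  iH <- match(highIds, clinical$sample_id)
  if (anyNA(iL) || anyNA(iH)) stop("sample ids missing from clinical table")
  tL <- clinical[[tcol]][iL]; eL <- clinical[[ecol]][iL]
  tH <- clinical[[tcol]][iH]; eH <- clinical[[ecol]][iH]
  switch(test,
         ranksum = ranksumTest(tL, tH),
         logrank = logrankTest(tL, eL, tH, eH),
         gehan = gehanWilcoxonTest(tL, eL, tH, eH))
}
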