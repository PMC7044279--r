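#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p under the hypergeometric null with fixed margins: the
#' sum of the probabilities of every table at least as extreme as (point
#' probability no larger than, within relative tolerance 1e-7) the observed
#' one. When a margin is zero the table carries no information and p = 1 is
#' returned with a \code{"degenerate"} attribute.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector (row-wise).
#' @return The two-sided p-value; attribute \code{"degenerate"} is TRUE for
#'   zero-margin tables.
#' @examples
#' fisherExact2x2(matrix(c(24, 136, 31, 41), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  m <- sum(tab[1L, ])          # margin of row 1
  n <- sum(tab[2L, ])          # margin of row 2
  k <- sum(tab[, 1L])          # margin of column 1
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2L]) == 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  pObs <- dhyper(x, m, n, k)
  p <- min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
  attr(p, "degenerate") <- FALSE
  p
}

## Build the covariate-level count frame used by the scan: one row per
## (covariate, level) with low/high counts. Age is dichotomized at the
## pooled median so it enters the same exact-test framework.
covariateLevelCounts <- function(lowIds, highIds, clinical, covariates) {
  iL <- match(lowIds, clinical$sample_id)
  iH <- match(highIds, clinical$sample_id)
  if (anyNA(iL) || anyNA(iH)) stop("sample ids missing from clinical table")
  rows <- list()
  for (cv in covariates) {
    if (cv == "age") {
      if (!"age" %in% colnames(clinical)) next
      age <- clinical$age
      pooledMed <- median(age[c(iL, iH)], na.rm = TRUE)
      v <- ifelse(is.na(age), "unknown",
                  ifelse(age > pooledMed, "above_median", "at_or_below_median"))
    } else {
      if (!cv %in% colnames(clinical)) next
      v <- as.character(clinical[[cv]])
      v[is.na(v)] <- "unknown"
    }
    vL <- v[iL]; vH <- v[iH]
    levs <- sort(unique(c(vL, vH)))
    if (length(levs) < 2L) next   # covariate constant across both groups
    for (lev in levs)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = lev,
        countLow = sum(vL == lev), countHigh = sum(vH == lev))
  }
  if (!length(rows))
    return(data.frame(covariate = character(), level = character(),
                      countLow = integer(), countHigh = integer()))
  do.call(rbind, rows)
}

#' Scan low/high subgroups for covariate imbalance
#'
#' For every level of every covariate, builds the one-vs-rest 2x2 table
#' (level / not-level against low / high group) and tests it with the
#' exact Fisher test. Age, the only continuous covariate, is dichotomized
#' at the pooled median first. Covariates constant across both groups are
#' skipped. Results are sorted by ascending p.
#'
#' @param lowIds,highIds Disjoint, non-empty sample-id sets.
#' @param clinical Clinical data.frame.
#' @param covariates Covariate column names; include \code{"age"} to test
#'   the age dichotomy. Defaults to the table's covariate attribute.
#' @param alpha Significance level used only for the \code{flagged} column.
#' @return data.frame(covariate, level, countLow, countHigh, p, flagged)
#'   sorted by p.
#' @export
imbalanceScan <- function(lowIds, highIds, clinical, covariates = NULL,
                          alpha = 0.05) {
  if (!length(lowIds) || !length(highIds)) stop("both groups must be non-empty")
  if (length(intersect(lowIds, highIds))) stop("groups must be disjoint")
  covariates <- covariates %||% attr(clinical, "covariates") %||%
    setdiff(colnames(clinical),
            c("sample_id", "os_time", "os_event", "efs_time", "efs_event"))
  counts <- covariateLevelCounts(lowIds, highIds, clinical, covariates)
  nL <- length(lowIds); nH <- length(highIds)
  counts$p <- vapply(seq_len(nrow(counts)), function(i) {
    as.numeric(fisherExact2x2(matrix(c(counts$countLow[i], nL - counts$countLow[i],
                                       counts$countHigh[i], nH - counts$countHigh[i]),
                                     2L, 2L, byrow = TRUE)))
  }, numeric(1L))
  counts$flagged <- counts$p < alpha
  counts[order(counts$p, counts$covariate, counts$level), , drop = FALSE]
}

#' Remove covariate imbalance by seeded randomized shuffling
#'
#' Iteratively balances the low/high expresser subgroups: at each
#' iteration the covariate scan is re-run; if no level is significant at
#' \code{alpha} the procedure stops converged. Otherwise the most
#' significant (covariate, level) is targeted: with probability 0.5, when
#' previously removed patients NOT carrying that level exist, one of them
#' (chosen uniformly) is re-admitted to the side it was removed from (the
#' under-represented direction); otherwise one uniformly chosen carrier of
#' the level is removed from the group where the level is over-represented.
#' The procedure never adds a patient that was not in the original groups,
#' and with the same seed its output is fully deterministic.
#'
#' @param lowIds,highIds Disjoint starting subgroups.
#' @param clinical Clinical data.frame.
#' @param covariates Covariate columns to balance on (see
#'   \code{\link{imbalanceScan}}).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer RNG seed.
#' @param maxIter Iteration cap (default 1000); on reaching it the
#'   best-found groups are returned with \code{converged = FALSE}, never an
#'   error.
#' @return A \linkS4class{BalanceReport}.
#' @export
rebalance <- function(lowIds, highIds, clinical, covariates = NULL,
                      alpha = 0.05, seed = 1L, maxIter = 1000L) {
  if (maxIter < 1L) stop("maxIter must be >= 1")
  if (length(intersect(lowIds, highIds))) stop("groups must be disjoint")
  covariates <- covariates %||% attr(clinical, "covariates") %||%
    setdiff(colnames(clinical),
            c("sample_id", "os_time", "os_event", "efs_time", "efs_event"))
  scanBefore <- imbalanceScan(lowIds, highIds, clinical, covariates, alpha)

  levelCarrier <- function(ids, cv, lev) {
    i <- match(ids, clinical$sample_id)
    if (cv == "age") {
      age <- clinical$age
      pooledMed <- median(age[match(c(lowIds, highIds), clinical$sample_id)],
                          na.rm = TRUE)
      v <- ifelse(is.na(age[i]), "unknown",
                  ifelse(age[i] > pooledMed, "above_median", "at_or_below_median"))
    } else {
      v <- as.character(clinical[[cv]][i])
      v[is.na(v)] <- "unknown"
    }
    v == lev
  }

  withSeed(seed, {
    low <- lowIds; high <- highIds
    removedLow <- character(); removedHigh <- character()
    trail <- list()
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
      scan <- imbalanceScan(low, high, clinical, covariates, alpha)
      if (!nrow(scan) || scan$p[1L] >= alpha) { converged <- TRUE; break }
      iter <- iter + 1L
      cv <- scan$covariate[1L]; lev <- scan$level[1L]
      propLow <- scan$countLow[1L] / length(low)
      propHigh <- scan$countHigh[1L] / length(high)
      overIsLow <- propLow > propHigh
      removedPool <- if (overIsLow) removedHigh else removedLow
      nonCarriers <- if (length(removedPool))
        removedPool[!levelCarrier(removedPool, cv, lev)] else character()
      readmit <- length(nonCarriers) > 0L && runif(1L) < 0.5
      if (readmit) {
        pick <- if (length(nonCarriers) == 1L) nonCarriers
                else sample(nonCarriers, 1L)
        if (overIsLow) {
          high <- c(high, pick); removedHigh <- setdiff(removedHigh, pick)
          grp <- "high"
        } else {
          low <- c(low, pick); removedLow <- setdiff(removedLow, pick)
          grp <- "low"
        }
        action <- "readmit"
      } else {
        over <- if (overIsLow) low else high
        carriers <- over[levelCarrier(over, cv, lev)]
        if (!length(carriers)) break   # nothing movable for this level
        pick <- if (length(carriers) == 1L) carriers else sample(carriers, 1L)
        if (overIsLow) {
          low <- setdiff(low, pick); removedLow <- c(removedLow, pick)
          grp <- "low"
        } else {
          high <- setdiff(high, pick); removedHigh <- c(removedHigh, pick)
          grp <- "high"
        }
        action <- "remove"
      }
      trail[[iter]] <- data.frame(iteration = iter, covariate = cv,
                                  level = lev, action = action,
                                  sample = pick, group = grp, p = scan$p[1L])
    }
    if (!converged && iter >= maxIter) {
      scan <- imbalanceScan(low, high, clinical, covariates, alpha)
      converged <- nrow(scan) == 0L || scan$p[1L] >= alpha
    }
    trailDf <- if (length(trail)) do.call(rbind, trail)
      else data.frame(iteration = integer(), covariate = character(),
                      level = character(), action = character(),
                      sample = character(), group = character(), p = numeric())
    methods::new("BalanceReport",
                 lowIds = low, highIds = high,
                 removedLow = removedLow, removedHigh = removedHigh,
                 scanBefore = scanBefore,
                 scanAfter = imbalanceScan(low, high, clinical, covariates, alpha),
                 trail = trailDf, iterations = iter,
                 converged = converged, seed = as.integer(seed),
                 alpha = alpha)
  })
}

#' Serialize a BalanceReport to JSON
#'
#' @param report A \linkS4class{BalanceReport}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeBalanceReport <- function(report, path) {
  stopifnot(methods::is(report, "BalanceReport"))
  jsonlite::write_json(list(
    converged = report@converged, iterations = report@iterations,
    seed = report@seed, alpha = report@alpha,
    low_ids = report@lowIds, high_ids = report@highIds,
    removed_low = report@removedLow, removed_high = report@removedHigh,
    scan_before = report@scanBefore, scan_after = report@scanAfter,
    trail = report@trail), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
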