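#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) to share one empirical distribution: each
#' column's values are replaced by the cross-column means of the order
#' statistics at the corresponding rank. Ties within a column receive the
#' mean of the reference values their positions span. Missing cells are
#' substituted with the column mean of available values before ranking and
#' restored to \code{NA} afterwards. The transform is idempotent.
#'
#' @param x Numeric probe-by-sample matrix.
#' @return Normalized matrix of the same shape and dimnames. A
#'   single-sample matrix is returned unchanged with a warning.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3, 5), b = c(2, 4, 6)))
#' @export
quantileNormalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(x)
  }
  filled <- x
  nas <- is.na(x)
  if (any(nas)) {
    colMean <- colMeans(x, na.rm = TRUE)
    idx <- which(nas, arr.ind = TRUE)
    filled[idx] <- colMean[idx[, 2L]]
  }
  sorted <- apply(filled, 2L, sort)
  ref <- rowMeans(sorted)
  out <- filled
  for (j in seq_len(ncol(filled))) {
    ord <- order(filled[, j])
    col <- numeric(nrow(filled))
    col[ord] <- ref
    # ties take the mean of the reference values their run spans
    col <- stats::ave(col, match(filled[, j], filled[, j]), FUN = mean)
    out[, j] <- col
  }
  out[nas] <- NA
  out
}

#' Estimate empirical-Bayes variance-moderation hyperparameters
#'
#' Fits the scaled-F model for per-probe sample variances, s^2 ~ s0^2 *
#' F(df, d0), by moment matching on the log scale: the mean and spread of
#' log s^2 are matched to their theoretical values through digamma /
#' trigamma identities, with the prior degrees of freedom d0 obtained by
#' Newton inversion of the trigamma function. When the observed spread of
#' the log variances does not exceed the chi-square sampling spread, d0 is
#' infinite (complete shrinkage to a single prior variance).
#'
#' @param variances Per-probe positive sample variances.
#' @param df Residual degrees of freedom shared by all probes.
#' @return A \linkS4class{ModerationParams}. With fewer than 30 probes the
#'   estimate is unstable and the function falls back to d0 = 0 (no
#'   moderation) with a warning.
#' @export
estimateModeration <- function(variances, df) {
  variances <- variances[!is.na(variances)]
  if (any(variances <= 0)) stop("variances must be positive")
  if (df < 1) stop("df must be >= 1")
  if (length(variances) < 30L) {
    warning("fewer than 30 probes: skipping moderation (d0 = 0)")
    return(methods::new("ModerationParams", d0 = 0, s0sq = median(variances)))
  }
  z <- log(variances)
  e <- z - digamma(df / 2) + log(df / 2)
  eMean <- mean(e)
  eVar <- var(e)
  excess <- eVar - trigamma(df / 2)
  if (excess <= 0)
    return(methods::new("ModerationParams", d0 = Inf, s0sq = exp(eMean)))
  d0 <- 2 * trigammaInverse(excess)
  s0sq <- exp(eMean + digamma(d0 / 2) - log(d0 / 2))
  methods::new("ModerationParams", d0 = d0, s0sq = s0sq)
}

## Newton inversion of the trigamma function: solve trigamma(y) = x, x > 0.
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated two-group t test per probe
#'
#' Empirical-Bayes two-sample comparison of high vs low expressers: the
#' pooled per-probe variance (df = nL + nH - 2) is shrunk toward the prior,
#' posterior s~^2 = (d0 s0^2 + df s^2) / (d0 + df), and the moderated
#' statistic t~ = (mean_high - mean_low) / (s~ sqrt(1/nL + 1/nH)) is
#' referred to a t distribution with d0 + df degrees of freedom (standard
#' normal when d0 + df exceeds 1e6, including the infinite-d0 limit). With
#' d0 = 0 this is exactly the classical pooled two-sample t test. Probes
#' with zero posterior variance but a non-zero mean difference get p = 0
#' and a degenerate flag.
#'
#' @param x Numeric probe-by-sample matrix (log2 scale, typically quantile
#'   normalized).
#' @param lowIds,highIds Sample-id vectors (each of size >= 2).
#' @param params A \linkS4class{ModerationParams}; when \code{NULL} the
#'   hyperparameters are estimated from the data with
#'   \code{\link{estimateModeration}}.
#' @return data.frame with one row per probe: probe_id, mean_low,
#'   mean_high, log2fc (= mean_high - mean_low), t_moderated, p_value,
#'   p_adjusted (BH), posterior_s2, flag.
#' @export
moderatedTTest <- function(x, lowIds, highIds, params = NULL) {
  stopifnot(is.matrix(x))
  if (length(lowIds) < 2L || length(highIds) < 2L)
    stop("both groups need at least 2 samples")
  if (!all(c(lowIds, highIds) %in% colnames(x)))
    stop("group sample ids missing from matrix columns")
  xL <- x[, lowIds, drop = FALSE]
  xH <- x[, highIds, drop = FALSE]
  nL <- length(lowIds); nH <- length(highIds)
  df <- nL + nH - 2
  mL <- rowMeans(xL); mH <- rowMeans(xH)
  ssL <- rowSums((xL - mL)^2)
  ssH <- rowSums((xH - mH)^2)
  s2 <- (ssL + ssH) / df
  if (is.null(params)) params <- estimateModeration(s2[s2 > 0], df)
  d0 <- params@d0; s0sq <- params@s0sq
  post <- if (is.infinite(d0)) rep(s0sq, length(s2))
          else (d0 * s0sq + df * s2) / (d0 + df)
  fc <- mH - mL
  se <- sqrt(post * (1 / nL + 1 / nH))
  tmod <- fc / se
  dfTotal <- d0 + df
  p <- if (is.finite(dfTotal) && dfTotal <= 1e6)
    2 * pt(abs(tmod), df = dfTotal, lower.tail = FALSE)
  else 2 * pnorm(abs(tmod), lower.tail = FALSE)
  flag <- rep("ok", length(s2))
  degen <- post <= 0
  if (any(degen)) {
    p[degen] <- ifelse(fc[degen] == 0, 1, 0)
    flag[degen] <- "degenerate"
    tmod[degen] <- ifelse(fc[degen] == 0, 0, Inf * sign(fc[degen]))
  }
  data.frame(probe_id = rownames(x), mean_low = mL, mean_high = mH,
             log2fc = fc, t_moderated = tmod, p_value = p,
             p_adjusted = bhAdjust(p), posterior_s2 = post,
             flag = flag, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false discovery rate: p-values are sorted ascending, the
#' i-th is multiplied by m/i, monotonicity is enforced from the largest
#' down, values are capped at 1, and the input order is restored.
#' Delegates to \code{stats::p.adjust(method = "BH")}, which implements
#' exactly this step-up rule.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order; element-wise >= input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Split differential-expression records into up/down gene lists
#'
#' The paper-style call: differential genes have |log2 FC| above
#' \code{fcCut} and BH-adjusted p below \code{qCut}, split by sign
#' (positive log2fc = elevated in the high-expresser group).
#'
#' @param records data.frame from \code{\link{moderatedTTest}}.
#' @param fcCut Absolute log2 fold-change cut (default 1; use 1.5 for the
#'   "most differential" volcano lists).
#' @param qCut Adjusted-p cut (default 0.05).
#' @return list(up_in_high, down_in_high) of probe ids.
#' @export
selectDEGenes <- function(records, fcCut = 1.0, qCut = 0.05) {
  stopifnot(nrow(records) > 0,
            all(c("probe_id", "log2fc", "p_adjusted") %in% colnames(records)))
  up <- records$probe_id[records$log2fc > fcCut & records$p_adjusted < qCut]
  down <- records$probe_id[records$log2fc < -fcCut & records$p_adjusted < qCut]
  list(up_in_high = up, down_in_high = down)
}
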