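#' Min-max scale one probe's expression to [0, 1]
#'
#' Affine rescaling of a probe's per-sample values so the cohort minimum
#' maps to 0 and the maximum to 1; missing values stay missing. Scaling is
#' invariant to positive affine transforms of the input, and deliberately
#' range-based rather than rank-based: the low/high expresser cut at
#' 0.3/0.7 slices the expression RANGE, so group sizes are generally
#' unequal. A rank-based alternative is available for sensitivity analysis.
#'
#' @param x Numeric vector (one probe across samples); names are preserved.
#' @param method \code{"minmax"} (default) or \code{"rank"} (mid-ranks
#'   mapped to [0,1]).
#' @return Numeric vector in [0,1] with the same names; \code{NA} passes
#'   through.
#' @examples
#' scaleProbe(c(2, 4, 6, 8, 10))
#' @export
scaleProbe <- function(x, method = c("minmax", "rank")) {
  method <- match.arg(method)
  obs <- x[!is.na(x)]
  if (length(obs) < 2L)
    stop("scaleProbe needs at least 2 non-missing values")
  if (method == "minmax") {
    rng <- range(obs)
    if (rng[2L] <= rng[1L]) degenerateProbeError(names(x)[1L] %||% "<unnamed>")
    out <- (x - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    if (max(obs) <= min(obs)) degenerateProbeError(names(x)[1L] %||% "<unnamed>")
    out <- rep(NA_real_, length(x))
    out[!is.na(x)] <- (rank(obs) - 1) / (length(obs) - 1)
    names(out) <- names(x)
  }
  out
}

#' Assign samples to low/high expresser subgroups
#'
#' Cuts the scaled expression range with closed intervals: samples with
#' scaled value \eqn{\le} \code{lowThreshold} are low expressers, samples
#' with scaled value \eqn{\ge} \code{highThreshold} are high expressers,
#' and samples strictly in between are "mid" and excluded. When either
#' group is smaller than \code{minGroup}, the assignment is flagged
#' \code{"underpowered"} (the genome-wide screen then skips the probe).
#'
#' @param scaled Named numeric vector in [0,1] (from
#'   \code{\link{scaleProbe}}); names are sample ids.
#' @param lowThreshold,highThreshold Range cut points, default 0.3 and 0.7.
#' @param minGroup Minimum informative group size (default 10).
#' @param probeId Probe identifier recorded on the assignment.
#' @return A \linkS4class{SubgroupAssignment}.
#' @examples
#' sc <- c(A = 0, B = 0.25, C = 0.3, D = 0.5, E = 0.7, F = 1)
#' assignSubgroups(sc, probeId = "P1", minGroup = 1)
#' @export
assignSubgroups <- function(scaled, lowThreshold = 0.3, highThreshold = 0.7,
                            minGroup = 10L, probeId = "probe") {
  if (!(lowThreshold >= 0 && lowThreshold < highThreshold && highThreshold <= 1))
    stop("thresholds must satisfy 0 <= low < high <= 1")
  if (is.null(names(scaled)))
    names(scaled) <- paste0("S", seq_along(scaled))
  if (any(scaled < -1e-9 | scaled > 1 + 1e-9, na.rm = TRUE))
    stop("scaled values must lie in [0,1]; run scaleProbe first")
  lo <- names(scaled)[!is.na(scaled) & scaled <= lowThreshold]
  hi <- names(scaled)[!is.na(scaled) & scaled >= highThreshold]
  flags <- character()
  if (length(lo) < minGroup || length(hi) < minGroup)
    flags <- "underpowered"
  methods::new("SubgroupAssignment", probeId = probeId, scaled = scaled,
               lowIds = lo, highIds = hi,
               lowThreshold = lowThreshold, highThreshold = highThreshold,
               flags = flags)
}

#' Tabulate a subgroup assignment as a per-sample data.frame
#'
#' @param assignment A \linkS4class{SubgroupAssignment}.
#' @return data.frame with columns \code{sample_id}, \code{group}
#'   (low/mid/high) and \code{scaled}.
#' @export
subgroupFrame <- function(assignment) {
  stopifnot(methods::is(assignment, "SubgroupAssignment"))
  ids <- names(assignment@scaled)
  grp <- rep("mid", length(ids))
  grp[ids %in% assignment@lowIds] <- "low"
  grp[ids %in% assignment@highIds] <- "high"
  data.frame(sample_id = ids, group = grp,
             scaled = unname(assignment@scaled))
}
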