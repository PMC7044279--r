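#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{code} with the global random-number state set from \code{seed}
#' and restores the previous state afterwards, so seeded package operations
#' (cohort simulation, rebalancing, permutation tests) never perturb the
#' caller's random stream.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## classed condition used by the screen to skip zero-range probes
degenerateProbeError <- function(probeId) {
  stop(errorCondition(
    sprintf("probe '%s' has zero expression range (constant across samples)",
            probeId),
    class = c("degenerateProbe", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats median na.omit quantile rbinom rchisq rexp rnorm runif
#' @importFrom stats cor cor.test dist hclust p.adjust pchisq pnorm pt sd var
#' @importFrom stats setNames cutree rank dhyper
#' @importFrom utils read.delim write.table head
NULL
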