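# Shared fixtures, built in code. The default seed-7 cohort and its screen
# are expensive enough to cache across test files.

.fixtureCache <- new.env(parent = emptyenv())

defaultCohort7 <- function() {
  if (is.null(.fixtureCache$cohort7))
    .fixtureCache$cohort7 <- generateCohort(SyntheticCohortSpec(seed = 7L))
  .fixtureCache$cohort7
}

defaultScreen7 <- function() {
  if (is.null(.fixtureCache$screen7))
    .fixtureCache$screen7 <- screenProbes(defaultCohort7())
  .fixtureCache$screen7
}

# A tiny deterministic cohort for structural tests.
smallCohort <- function(n = 40L, nProbes = 12L, seed = 42L) {
  generateCohort(SyntheticCohortSpec(
    nPatients = n, nProbes = nProbes, moduleSize = 3L, seed = seed))
}

# Minimal hand-written clinical table.
tinyClinical <- function() {
  df <- data.frame(
    sample_id = paste0("S", 1:8),
    os_time = c(5, 10, 15, 20, 25, 30, 35, 40),
    os_event = c(1, 1, 0, 1, 0, 1, 1, 0),
    mutA = factor(c("yes", "yes", "yes", "no", "no", "no", "no", "no")))
  attr(df, "covariates") <- "mutA"
  df
}
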