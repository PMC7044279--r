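#' Construct a synthetic-cohort specification
#'
#' Parameterizes a simulated AML-like cohort with the statistical structure
#' the screen assumes: a latent per-patient level z ~ Uniform(0,1) drives
#' one planted biomarker probe (slope \code{biomarkerBeta} log2 units), a
#' co-expressed downstream module of \code{moduleSize} genes at slope
#' \code{moduleLog2fc}, proportional-hazards survival (event times
#' Weibull with scale exp(-hazardLogHr z / shape) on the baseline hazard;
#' shape 1 = exponential), independent exponential censoring, and binary
#' mutation-like covariates whose prevalence is linear in z (so range-based
#' subgrouping induces the covariate imbalances the balancing stage must
#' remove). An additional FAB-like categorical factor is survival-neutral.
#'
#' Defaults give a 200-patient, 2000-probe cohort with biomarker slope 3
#' over noise sd 0.7, log hazard ratio 1.1 per unit z on a 0.02/month
#' baseline hazard with 0.01/month censoring, a 30-gene module at log2 fold
#' change 2, and two confounders: an NPM1c-like lesion (prevalence
#' 0.15 + 0.30 z, enriched in high expressers) and a CEBPA-like lesion
#' (0.12 - 0.12 z, enriched in low expressers).
#'
#' @param nPatients,nProbes Cohort dimensions (defaults 200, 2000).
#' @param biomarkerBeta Biomarker expression slope on z (default 3.0).
#' @param baselineSd Expression noise sd (default 0.7).
#' @param hazardLogHr Log hazard ratio per unit z (default 1.1).
#' @param baselineHazard Baseline event hazard per month (default 0.02).
#' @param censorHazard Censoring hazard per month (default 0.01).
#' @param efsHazardFactor EFS baseline-hazard multiplier (default 1.3).
#' @param weibullShape Event-time Weibull shape (default 1 = exponential).
#' @param moduleSize,moduleLog2fc Planted module size and slope (30, 2.0).
#' @param confounders data.frame(name, base_prevalence, prevalence_slope).
#' @param nCovariateLevels Levels of the survival-neutral factor (default 5).
#' @param seed Integer RNG seed.
#' @return A \linkS4class{SyntheticCohortSpec}.
#' @examples
#' SyntheticCohortSpec(seed = 7L)
#' @export
SyntheticCohortSpec <- function(nPatients = 200L, nProbes = 2000L,
                                biomarkerBeta = 3.0, baselineSd = 0.7,
                                hazardLogHr = 1.1, baselineHazard = 0.02,
                                censorHazard = 0.01, efsHazardFactor = 1.3,
                                weibullShape = 1, moduleSize = 30L,
                                moduleLog2fc = 2.0,
                                confounders = data.frame(
                                  name = c("NPM1c_like", "CEBPA_like"),
                                  base_prevalence = c(0.15, 0.12),
                                  prevalence_slope = c(0.30, -0.12)),
                                nCovariateLevels = 5L, seed = 1L) {
  methods::new("SyntheticCohortSpec",
               nPatients = as.integer(nPatients), nProbes = as.integer(nProbes),
               biomarkerBeta = biomarkerBeta, baselineSd = baselineSd,
               hazardLogHr = hazardLogHr, baselineHazard = baselineHazard,
               censorHazard = censorHazard, efsHazardFactor = efsHazardFactor,
               weibullShape = weibullShape, moduleSize = as.integer(moduleSize),
               moduleLog2fc = moduleLog2fc, confounders = confounders,
               nCovariateLevels = as.integer(nCovariateLevels),
               seed = as.integer(seed))
}

specAsList <- function(spec) {
  list(nPatients = spec@nPatients, nProbes = spec@nProbes,
       biomarkerBeta = spec@biomarkerBeta, baselineSd = spec@baselineSd,
       hazardLogHr = spec@hazardLogHr, baselineHazard = spec@baselineHazard,
       censorHazard = spec@censorHazard, efsHazardFactor = spec@efsHazardFactor,
       weibullShape = spec@weibullShape, moduleSize = spec@moduleSize,
       moduleLog2fc = spec@moduleLog2fc,
       confounders = spec@confounders,
       nCovariateLevels = spec@nCovariateLevels, seed = spec@seed)
}

#' Read/write a SyntheticCohortSpec as YAML
#'
#' @param spec A \linkS4class{SyntheticCohortSpec}.
#' @param path YAML path.
#' @return \code{writeCohortSpec}: \code{path} invisibly;
#'   \code{readCohortSpec}: the spec.
#' @export
writeCohortSpec <- function(spec, path) {
  yaml::write_yaml(specAsList(spec), path)
  invisible(path)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
  lst <- yaml::read_yaml(path)
  cf <- lst$confounders
  if (!is.null(cf) && !is.data.frame(cf))
    cf <- as.data.frame(cf)   # yaml stores data.frames column-major
  do.call(SyntheticCohortSpec, c(
    lst[setdiff(names(lst), "confounders")],
    if (!is.null(cf)) list(confounders = cf)))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Simulates the cohort described by the spec (see
#' \code{\link{SyntheticCohortSpec}}). Per patient i: latent
#' z_i ~ Uniform(0,1); the biomarker probe is mu + biomarkerBeta z_i +
#' Normal(0, baselineSd); each module probe is mu_g + moduleLog2fc z_i +
#' noise; null probes are mu_g + noise. Overall survival is min(T_i, C_i)
#' with T_i proportional-hazards Weibull (hazard baselineHazard
#' exp(hazardLogHr z_i); shape 1 = exponential), C_i ~
#' Exponential(censorHazard) and event flag [T_i <= C_i]; EFS is generated
#' the same way from its own draws with an \code{efsHazardFactor}-scaled
#' baseline hazard. Binary confounders are Bernoulli with probability
#' base_prevalence + prevalence_slope z_i (clipped to [0,1] with a warning
#' when clipping occurs); the FAB-like factor is uniform over its levels
#' and survival-neutral. The truth record (latent z, probe roles, all
#' parameters) is stored in \code{metadata(cohort)$truth}.
#'
#' Identical specs (including the seed) produce identical cohorts.
#'
#' @param spec A \linkS4class{SyntheticCohortSpec}.
#' @return A \linkS4class{ScreenCohort}.
#' @export
generateCohort <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticCohortSpec"))
  methods::validObject(spec)
  withSeed(spec@seed, {
    n <- spec@nPatients; G <- spec@nProbes
    ids <- sprintf("S%03d", seq_len(n))
    z <- runif(n)
    biomarkerId <- "PROBE_BM"
    nModule <- spec@moduleSize
    moduleIds <- if (nModule) sprintf("PROBE_MOD%03d", seq_len(nModule)) else character()
    nNull <- G - 1L - nModule
    nullIds <- if (nNull > 0L) sprintf("PROBE_NULL%04d", seq_len(nNull)) else character()
    probes <- c(biomarkerId, moduleIds, nullIds)
    mu <- rnorm(G, mean = 7, sd = 1.5)          # per-probe baseline (log2)
    slope <- c(spec@biomarkerBeta, rep(spec@moduleLog2fc, nModule),
               rep(0, max(0L, nNull)))
    x <- mu + outer(slope, z) +
      matrix(rnorm(G * n, sd = spec@baselineSd), G, n)
    dimnames(x) <- list(probes, ids)

    hazScale <- function(base) {
      # inverse-cdf draw from a PH Weibull: S(t) = exp(-base*exp(b z)*t^shape)
      u <- runif(n)
      (-log(u) / (base * exp(spec@hazardLogHr * z)))^(1 / spec@weibullShape)
    }
    tOs <- hazScale(spec@baselineHazard)
    cOs <- rexp(n, rate = spec@censorHazard)
    tEfs <- hazScale(spec@baselineHazard * spec@efsHazardFactor)
    cEfs <- rexp(n, rate = spec@censorHazard)
    clinical <- data.frame(
      sample_id = ids,
      os_time = pmin(tOs, cOs), os_event = as.integer(tOs <= cOs),
      efs_time = pmin(tEfs, cEfs), efs_event = as.integer(tEfs <= cEfs),
      age = round(pmax(18, rnorm(n, 55, 12)), 1),
      sex = factor(sample(c("M", "F"), n, replace = TRUE)))
    covs <- character()
    cf <- spec@confounders
    for (i in seq_len(nrow(cf))) {
      pr <- cf$base_prevalence[i] + cf$prevalence_slope[i] * z
      if (any(pr < 0 | pr > 1))
        warning(sprintf("confounder '%s': prevalence clipped to [0,1]", cf$name[i]))
      pr <- pmin(1, pmax(0, pr))
      clinical[[cf$name[i]]] <- factor(ifelse(rbinom(n, 1L, pr) == 1L, "yes", "no"),
                                       levels = c("no", "yes"))
      covs <- c(covs, cf$name[i])
    }
    if (spec@nCovariateLevels > 1L) {
      clinical$FAB <- factor(sample(paste0("M", seq_len(spec@nCovariateLevels) - 1L),
                                    n, replace = TRUE))
      covs <- c(covs, "FAB")
    }
    covs <- c(covs, "sex", "age")
    attr(clinical, "covariates") <- covs
    cohort <- ScreenCohort(x, clinical, covariates = covs)
    S4Vectors::metadata(cohort)$truth <- list(
      z = setNames(z, ids), biomarker = biomarkerId, module = moduleIds,
      nulls = nullIds, spec = specAsList(spec))
    cohort
  })
}

#' Ground-truth recovery summary for a synthetic cohort
#'
#' Compares pipeline outputs produced on a generated cohort against the
#' cohort's planted truth: the biomarker's rank in the screen, module
#' recall/precision in the differential lists, the estimated vs planted
#' module log2 fold change, balancing convergence and the module gene-set
#' GSEA p-value.
#'
#' @param cohort A cohort from \code{\link{generateCohort}} (its metadata
#'   must carry the truth record).
#' @param screen Optional \linkS4class{ScreenResult} computed on the cohort.
#' @param dge Optional data.frame from \code{\link{moderatedTTest}}.
#' @param deLists Optional list from \code{\link{selectDEGenes}}.
#' @param balance Optional \linkS4class{BalanceReport}; its groups are also
#'   used for the dose-normalized fold-change estimate.
#' @param gsea Optional \linkS4class{GSEAResult}.
#' @param groups Optional list(low, high) of sample ids used for the DE
#'   contrast (defaults to the balance report's groups). Needed to
#'   normalize the module fold-change estimate.
#' @return Named list of recovery metrics; entries for outputs not supplied
#'   are omitted. Module precision is NA when nothing was selected.
#'   \code{module_log2fc_contrast} is the raw high-minus-low group
#'   difference averaged over module genes; because the planted module
#'   fold change is a slope per unit latent level and the expresser groups
#'   span only part of the latent range, the slope itself is recovered as
#'   \code{module_log2fc_per_unit} = contrast / (difference in mean
#'   min-max-scaled biomarker expression between the groups).
#' @export
truthReport <- function(cohort, screen = NULL, dge = NULL, deLists = NULL,
                        balance = NULL, gsea = NULL, groups = NULL) {
  truth <- S4Vectors::metadata(cohort)$truth
  if (is.null(truth)) stop("cohort carries no truth record")
  out <- list(biomarker = truth$biomarker, module_size = length(truth$module))
  if (!is.null(screen)) {
    tab <- screenTable(screen)
    if (!truth$biomarker %in% tab$probe_id)
      stop("screen result does not match the cohort (biomarker probe absent)")
    ok <- tab[tab$flag == "ok", , drop = FALSE]
    out$biomarker_rank <- if (truth$biomarker %in% ok$probe_id)
      which(ok$probe_id[order(ok$p_os)] == truth$biomarker) else NA_integer_
    out$biomarker_p_os <- tab$p_os[tab$probe_id == truth$biomarker]
  }
  if (!is.null(dge)) {
    mod <- dge[dge$probe_id %in% truth$module, , drop = FALSE]
    out$module_log2fc_contrast <- mean(mod$log2fc)
    if (is.null(groups) && !is.null(balance))
      groups <- list(low = lowIds(balance), high = highIds(balance))
    if (!is.null(groups)) {
      sc <- scaleProbe(exprsMatrix(cohort)[truth$biomarker, ])
      dose <- mean(sc[groups$high]) - mean(sc[groups$low])
      out$module_log2fc_per_unit <- out$module_log2fc_contrast / dose
    }
  }
  if (!is.null(deLists)) {
    sel <- unique(c(deLists$up_in_high, deLists$down_in_high))
    sel <- setdiff(sel, truth$biomarker)   # planted biomarker is not module truth
    out$module_recall <- if (length(truth$module))
      mean(truth$module %in% sel) else NA_real_
    out$module_precision <- if (length(sel)) mean(sel %in% truth$module)
      else NA_real_
  }
  if (!is.null(balance)) {
    out$balance_converged <- converged(balance)
    out$balance_min_p_after <- if (nrow(balance@scanAfter))
      min(balance@scanAfter$p) else NA_real_
  }
  if (!is.null(gsea)) out$gsea_p <- gsea@pPerm
  out
}
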