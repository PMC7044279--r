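#' Run the full biomarker-screening pipeline
#'
#' Orchestrates the whole workflow as one reproducible run: screen every
#' probe, select hits, then for the designated probe (or the top hit)
#' subgroup, rebalance covariates, re-test survival on the balanced groups,
#' quantile-normalize, run moderated differential expression, cluster
#' patients and genes, and run GSEA for each supplied gene set. All stage
#' outputs (TSV/JSON/Newick) and a JSON run manifest (config hash, stage
#' order, per-stage seeds and wall clock, row counts) are written under the
#' output directory. One global seed derives per-stage seeds by fixed
#' offsets (+1 balancing, +2 GSEA) so stages are individually reproducible.
#' Any stage failure aborts with the stage name; outputs of completed
#' stages are preserved.
#'
#' @param config A named list or the path of a YAML file with entries:
#'   either \code{synthetic} (a SyntheticCohortSpec YAML block / spec list)
#'   or \code{expression_path} + \code{clinical_path}; optional
#'   \code{gmt_path}; \code{output_dir} (required); optional
#'   \code{designated_probe}, \code{low_threshold} (0.3),
#'   \code{high_threshold} (0.7), \code{min_group} (10), \code{test}
#'   ("ranksum"), \code{alpha} (0.05), \code{require_both},
#'   \code{covariates}, \code{max_iter} (1000), \code{fc_cut} (1),
#'   \code{q_cut} (0.05), \code{n_perm} (1000), \code{seed} (1).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  configPath <- NULL
  if (is.character(config) && length(config) == 1L) {
    configPath <- config
    if (!file.exists(configPath)) stop("config file not found: ", configPath)
    config <- yaml::read_yaml(configPath)
  }
  stopifnot(is.list(config))
  outDir <- config$output_dir %||% stop("config needs 'output_dir'")
  for (p in c(config$expression_path, config$clinical_path, config$gmt_path))
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  test <- config$test %||% "ranksum"
  alpha <- config$alpha %||% 0.05

  # stable config hash: canonical JSON of the config itself
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfgFile <- file.path(outDir, "config.json")
  writeLines(cfgJson, cfgFile)
  cfgHash <- unname(tools::md5sum(cfgFile))

  manifest <- list(package = "SurvScreen",
                   version = as.character(utils::packageVersion("SurvScreen")),
                   config_hash = cfgHash, seed = seed,
                   seeds = list(balance = seed + 1L, gsea = seed + 2L),
                   stages = list())
  t0 <- NULL
  stage <- function(name, expr) {
    t0 <<- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  cohort <- stage("load", {
    if (!is.null(config$synthetic)) {
      sp <- if (methods::is(config$synthetic, "SyntheticCohortSpec"))
        config$synthetic
      else do.call(SyntheticCohortSpec, config$synthetic)
      generateCohort(sp)
    } else {
      x <- readExpressionMatrix(config$expression_path)
      clin <- readClinicalTable(config$clinical_path,
                                covariates = config$covariates)
      ScreenCohort(x, clin)
    }
  })
  geneSets <- if (!is.null(config$gmt_path)) readGMT(config$gmt_path) else NULL
  manifest$n_probes <- nrow(cohort)
  manifest$n_samples <- ncol(cohort)

  screen <- stage("screen", screenProbes(
    cohort, lowThreshold = config$low_threshold %||% 0.3,
    highThreshold = config$high_threshold %||% 0.7,
    minGroup = config$min_group %||% 10L, test = test, alpha = alpha))
  writeScreenResult(screen, file.path(outDir, "screen.tsv"))
  manifest$stages$screen$n_rows <- nrow(screenTable(screen))

  hits <- stage("select_hits", selectHits(
    screen, alpha = alpha, requireBoth = config$require_both %||% NULL,
    allowlist = config$allowlist %||% NULL))
  write.table(hits, file.path(outDir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$select_hits$n_rows <- nrow(hits)

  probe <- config$designated_probe %||%
    (if (nrow(hits)) hits$probe_id[1L] else NULL)
  if (is.null(probe)) {
    warning("no hit to profile; pipeline stops after the screen")
    manifest$designated_probe <- NULL
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  manifest$designated_probe <- probe
  clin <- clinicalTable(cohort)
  x <- exprsMatrix(cohort)

  asg <- stage("subgroup", {
    a <- assignSubgroups(scaleProbe(x[probe, ]),
                         config$low_threshold %||% 0.3,
                         config$high_threshold %||% 0.7,
                         config$min_group %||% 10L, probe)
    write.table(subgroupFrame(a), file.path(outDir, "subgroups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    a
  })

  bal <- stage("balance", {
    b <- rebalance(lowIds(asg), highIds(asg), clin,
                   covariates = config$covariates %||% covariateNames(cohort),
                   alpha = alpha, seed = seed + 1L,
                   maxIter = config$max_iter %||% 1000L)
    writeBalanceReport(b, file.path(outDir, "balance.json"))
    b
  })
  manifest$balance_converged <- converged(bal)

  surv <- stage("survival_retest", {
    res <- list()
    for (ep in intersect(c("os", "efs"),
                         sub("_time$", "", grep("_time$", colnames(clin), value = TRUE)))) {
      iL <- match(lowIds(bal), clin$sample_id)
      iH <- match(highIds(bal), clin$sample_id)
      kmL <- kmEstimate(clin[[paste0(ep, "_time")]][iL], clin[[paste0(ep, "_event")]][iL])
      kmH <- kmEstimate(clin[[paste0(ep, "_time")]][iH], clin[[paste0(ep, "_event")]][iH])
      res[[ep]] <- list(
        p_ranksum = compareSurvival(clin, lowIds(bal), highIds(bal), ep, "ranksum")@pValue,
        p_logrank = compareSurvival(clin, lowIds(bal), highIds(bal), ep, "logrank")@pValue,
        median_low = survMedian(kmL), median_high = survMedian(kmH),
        n = c(length(iL), length(iH)))
      write.table(kmFrame(kmL), file.path(outDir, sprintf("km_%s_low.csv", ep)),
                  sep = ",", quote = FALSE, row.names = FALSE)
      write.table(kmFrame(kmH), file.path(outDir, sprintf("km_%s_high.csv", ep)),
                  sep = ",", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(res, file.path(outDir, "survival_retest.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })
  manifest$post_balance_p_os <- surv$os$p_ranksum

  dge <- stage("diffexp", {
    xn <- quantileNormalize(x)
    d <- moderatedTTest(xn, lowIds(bal), highIds(bal))
    write.table(d, file.path(outDir, "dge.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    d
  })
  deLists <- stage("select_de", {
    lst <- selectDEGenes(dge, fcCut = config$fc_cut %||% 1.0,
                         qCut = config$q_cut %||% 0.05)
    writeLines(lst$up_in_high, file.path(outDir, "de_up_in_high.txt"))
    writeLines(lst$down_in_high, file.path(outDir, "de_down_in_high.txt"))
    lst
  })
  manifest$n_de_up <- length(deLists$up_in_high)
  manifest$n_de_down <- length(deLists$down_in_high)

  deGenes <- setdiff(unique(c(deLists$up_in_high, deLists$down_in_high)), probe)
  if (length(deGenes) >= 2L) {
    stage("clustering", {
      sub <- x[deGenes, c(lowIds(bal), highIds(bal)), drop = FALSE]
      pc <- clusterPatients(sub)
      dendrogramNewick(pc$hclust, file.path(outDir, "patients.nwk"))
      write.table(pc$correlation, file.path(outDir, "patient_correlation.tsv"),
                  sep = "\t", quote = FALSE)
      gc <- clusterGenes(sub)
      dendrogramNewick(gc$hclust, file.path(outDir, "genes.nwk"))
      NULL
    })
  }
  if (!is.null(geneSets)) {
    gsea <- stage("gsea", {
      lapply(names(geneSets), function(nm)
        gseaPermutation(x, lowIds(bal), highIds(bal), geneSets[[nm]],
                        setName = nm, nPerm = config$n_perm %||% 1000L,
                        seed = seed + 2L))
    })
    jsonlite::write_json(
      lapply(gsea, function(g) list(set = g@setName, es = g@es, nes = g@nes,
                                    p_perm = g@pPerm,
                                    leading_edge = g@leadingEdge)),
      file.path(outDir, "gsea.json"), auto_unbox = TRUE, digits = NA)
    manifest$gsea_p <- setNames(vapply(gsea, function(g) g@pPerm, numeric(1L)),
                                vapply(gsea, function(g) g@setName, character(1L)))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
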