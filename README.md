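# SurvScreen

Genome-wide survival screening of expression biomarkers in AML cohorts.

## What this package is for

Clinical microarray cohorts of acute myeloid leukaemia (AML) pair a
probe-by-sample log2 expression matrix with per-patient overall survival
(OS), event-free survival (EFS) and mutation/karyotype covariates.
SurvScreen implements, as tested and reusable R functions, an unbiased
screen for single-gene prognostic biomarkers in such cohorts, for
bioinformaticians and biostatisticians who want the whole chain — from
raw matrix to enrichment analysis — reproducible under one seed.

The screen, per probe *g* with intensities $x_{gi}$:

1. min–max scale: $\tilde x_{gi} = (x_{gi}-\min_i x_{gi})/(\max_i x_{gi}-\min_i x_{gi})$;
2. split the expression **range**: low expressers $\tilde x \le 0.3$,
   high expressers $\tilde x \ge 0.7$ (closed intervals, unequal group
   sizes by design);
3. compare the groups' survival: two-sided Wilcoxon rank-sum on observed
   times by default, log-rank
   $\chi^2 = \left(\sum_t d_{1t} - \tfrac{d_t n_{1t}}{n_t}\right)^2 / \sum_t V_t$
   and Gehan–Wilcoxon as alternatives, with Kaplan–Meier medians per group;
4. call hits at raw $p<0.05$ on both endpoints (BH-FDR q-values reported
   alongside).

For a chosen hit the pipeline then removes covariate confounding by a
seeded randomized shuffle driven by per-level two-sided **Fisher exact
tests** (stop when every level has $p \ge \alpha$), re-tests survival,
runs quantile normalization plus **empirical-Bayes moderated-t**
differential expression
($\tilde s_g^2 = (d_0 s_0^2 + df\, s_g^2)/(d_0+df)$, hyperparameters by
log-variance moment matching), clusters patients ($1-r$ Pearson distance,
complete linkage) and genes (z-score Euclidean), and scores gene sets by
**GSEA** (signal-to-noise ranking, weighted-KS enrichment score,
phenotype-permutation p). A synthetic-cohort generator with planted
ground truth (latent level → biomarker probe, co-expressed module,
proportional-hazards survival, z-linked confounders) makes every stage
testable without any external data.

## Worked example

```r
library(SurvScreen)

## published 232-patient cohort table: NPM1c carriers 24/160 low vs 31/72 high
fisherExact2x2(matrix(c(24, 136, 31, 41), 2, byrow = TRUE))
#> [1] 8.951397e-06

## synthetic cohort with a planted biomarker and 30-gene module
spec   <- SyntheticCohortSpec(nPatients = 120L, nProbes = 300L, seed = 7L)
cohort <- generateCohort(spec)
screen <- screenProbes(cohort)
screen
#> ScreenResult: 300 probes; 237 tested, 63 skipped
#>   test: ranksum  thresholds: 0.3 / 0.7
#>  top probe: PROBE_MOD005 (p_os = 0.00039)

tab <- screenTable(screen)
head(tab[order(tab$p_os), c("probe_id", "n_low", "n_high", "p_os",
                            "median_os_low", "median_os_high")], 3)
#>       probe_id n_low n_high     p_os median_os_low median_os_high
#> 6 PROBE_MOD005    17     28 0.000390          43.7           6.30
#> 1     PROBE_BM    27     24 0.000614          29.0           7.97
#> 9 PROBE_MOD008    27     16 0.000953          29.0           7.30

truth <- S4Vectors::metadata(cohort)$truth
asg <- assignSubgroups(scaleProbe(exprsMatrix(cohort)[truth$biomarker, ]),
                       probeId = truth$biomarker)
bal <- rebalance(lowIds(asg), highIds(asg), clinicalTable(cohort), seed = 8L)
bal
#> BalanceReport: converged after 0 iterations (alpha = 0.05 )
#>   groups: low 27 (removed 0), high 24 (removed 0)
#>  smallest covariate p after balancing: 0.1269

gseaPermutation(exprsMatrix(cohort), lowIds(bal), highIds(bal),
                truth$module, setName = "planted_module",
                nPerm = 1000L, seed = 9L)
#> GSEAResult 'planted_module': ES = 0.993, NES = 1.967, p_perm = 0.000999 (1000 permutations)
#>  leading edge: 30 genes
```

Reading the numbers: the Fisher p reproduces the published cohort's
NPM1c imbalance to its printed precision. In the simulated cohort the
survival screen tests 237 of 300 probes (the rest have an extreme group
below the minimum size), the planted hazard-raising biomarker and its
co-expressed module genes top the ranking with `high_worse` direction
(high expressers' median OS ~8 vs ~29 months), the low/high groups are
already covariate-balanced at this size (0 shuffle iterations), and the
planted 30-gene module is maximally enriched with the smallest p the
permutation scheme can produce (1/1001).

The full orchestrated run — screen → hits → balancing → survival re-test
→ DE → clustering → GSEA, with a JSON manifest — is `runPipeline()`
(YAML config; thin wrapper in `inst/scripts/run-pipeline.R`).

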