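test_that("Fisher exact p reproduces published AML subgroup contingencies", {
  # NPM1c carriers: 24/160 low vs 31/72 high expressers
  expect_equal(as.numeric(fisherExact2x2(matrix(c(24, 136, 31, 41), 2, byrow = TRUE))),
               8.95e-06, tolerance = 5e-3)
  expect_equal(as.numeric(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))), 1)
  # both extreme tables of the hypergeometric: 2 / C(20,10)
  expect_equal(as.numeric(fisherExact2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))),
               2 / choose(20, 10), tolerance = 1e-12)
  pDeg <- fisherExact2x2(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_equal(as.numeric(pDeg), 1)
  expect_true(attr(pDeg, "degenerate"))
})

test_that("Fisher p equals hypergeometric enumeration for tables with total <= 60", {
  set.seed(10)
  for (i in 1:60) {
    repeat {
      tot <- sample(4:60, 1)
      cnt <- as.vector(stats::rmultinom(1, tot, runif(4, 0.05, 1)))
      tab <- matrix(cnt, 2, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(as.numeric(fisherExact2x2(tab)), bruteFisherP(tab),
                 tolerance = 1e-9)
    expect_equal(as.numeric(fisherExact2x2(tab)),
                 fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("imbalance scan builds one-vs-rest tables per covariate level", {
  clin <- data.frame(
    sample_id = paste0("S", 1:200),
    os_time = rep(10, 200), os_event = rep(1, 200),
    FAB = factor(rep(c("M1", "M2", "M4"), length.out = 200)),
    marker = factor(c(rep("yes", 30), rep("no", 70), rep("yes", 30), rep("no", 70))))
  attr(clin, "covariates") <- c("FAB", "marker")
  low <- paste0("S", 1:100); high <- paste0("S", 101:200)
  scan <- imbalanceScan(low, high, clin)
  # equal 30/100 proportions: marker must not be flagged
  expect_false(any(scan$flagged[scan$covariate == "marker"]))
  expect_true(all(scan$p[scan$covariate == "marker"] >= 1 - 1e-9))
  # 3-level FAB emits exactly 3 one-vs-rest tests
  expect_equal(sum(scan$covariate == "FAB"), 3L)
  expect_equal(nrow(scan), 5L)
  expect_false(is.unsorted(scan$p))
})

test_that("imbalance scan flags the published CEBPA imbalance", {
  clin <- data.frame(
    sample_id = paste0("S", 1:232),
    os_time = rep(1, 232), os_event = rep(1, 232),
    CEBPA = factor(c(rep("yes", 18), rep("no", 142), rep("no", 72))))
  attr(clin, "covariates") <- "CEBPA"
  scan <- imbalanceScan(paste0("S", 1:160), paste0("S", 161:232), clin)
  yes <- scan[scan$level == "yes", ]
  expect_equal(yes$p, 0.00112984, tolerance = 1e-4)
  expect_true(yes$flagged)
})

test_that("rebalancing removes a planted 50/100 vs 5/50 imbalance", {
  clin <- data.frame(
    sample_id = paste0("S", 1:150),
    os_time = rexp(150, 0.05), os_event = rbinom(150, 1, 0.8),
    lesion = factor(c(rep("yes", 50), rep("no", 50), rep("yes", 5), rep("no", 45))))
  attr(clin, "covariates") <- "lesion"
  low <- paste0("S", 1:100); high <- paste0("S", 101:150)
  rep1 <- rebalance(low, high, clin, alpha = 0.05, seed = 1L, maxIter = 200L)
  expect_true(converged(rep1))
  expect_lte(rep1@iterations, 200L)
  expect_true(all(rep1@scanAfter$p >= 0.05))
  # self-consistency: rescanning the returned groups reproduces p >= alpha
  rescan <- imbalanceScan(lowIds(rep1), highIds(rep1), clin)
  expect_gte(min(rescan$p), 0.05)
  # no invented patients
  expect_true(all(c(lowIds(rep1), highIds(rep1)) %in% c(low, high)))
  expect_length(intersect(lowIds(rep1), highIds(rep1)), 0L)
  # audit trail is monotone and names the acted-upon covariate
  expect_identical(rep1@trail$iteration, seq_len(nrow(rep1@trail)))
  expect_true(all(rep1@trail$covariate == "lesion"))
  # identical seed => identical report
  rep2 <- rebalance(low, high, clin, alpha = 0.05, seed = 1L, maxIter = 200L)
  expect_equal(rep1, rep2)
})

test_that("already balanced groups are a fixed point of rebalancing", {
  clin <- data.frame(
    sample_id = paste0("S", 1:80),
    os_time = rep(5, 80), os_event = rep(1, 80),
    mut = factor(rep(c("yes", "no"), 40)))
  attr(clin, "covariates") <- "mut"
  low <- paste0("S", 1:40); high <- paste0("S", 41:80)
  rep0 <- rebalance(low, high, clin, seed = 3L)
  expect_true(converged(rep0))
  expect_identical(rep0@iterations, 0L)
  expect_setequal(lowIds(rep0), low)
  expect_setequal(highIds(rep0), high)
})

test_that("maxIter exhaustion returns best-found groups, not an error", {
  clin <- data.frame(
    sample_id = paste0("S", 1:60),
    os_time = rep(1, 60), os_event = rep(1, 60),
    lesion = factor(c(rep("yes", 30), rep("no", 10), rep("no", 20))))
  attr(clin, "covariates") <- "lesion"
  rep0 <- rebalance(paste0("S", 1:40), paste0("S", 41:60), clin,
                    seed = 2L, maxIter = 1L)
  expect_s4_class(rep0, "BalanceReport")
  expect_identical(rep0@iterations, 1L)
})
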