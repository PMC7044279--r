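test_that("Kaplan-Meier product-limit estimate on hand-checked inputs", {
  km <- kmEstimate(1:5, rep(1, 5))
  expect_equal(km@survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(survMedian(km), 3)

  km <- kmEstimate(c(2, 5, 9), c(0, 0, 0))
  expect_length(km@time, 0L)
  expect_true(is.na(survMedian(km)))

  # one censored at 2: S(1) = 2/3, then the last subject dies -> S(3) = 0
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km@time, c(1, 3))
  expect_equal(km@survival, c(2 / 3, 0))

  expect_error(kmEstimate(numeric(), integer()), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(2)
  for (i in 1:10) {
    t <- round(rexp(25, 0.1), 2)
    km <- kmEstimate(t, rep(1, 25))
    emp <- vapply(km@time, function(tt) mean(t > tt), numeric(1))
    expect_equal(km@survival, emp, tolerance = 1e-12)
  }
})

test_that("KM estimate matches survival::survfit under censoring", {
  skip_if_not_installed("survival")
  set.seed(3)
  t <- rexp(60, 0.05); c <- rexp(60, 0.03)
  obs <- pmin(t, c); ev <- as.integer(t <= c)
  km <- kmEstimate(obs, ev)
  sf <- survival::survfit(survival::Surv(obs, ev) ~ 1)
  sfEvent <- sf$n.event > 0
  expect_equal(km@time, sf$time[sfEvent], tolerance = 1e-12)
  expect_equal(km@survival, sf$surv[sfEvent], tolerance = 1e-12)
  expect_equal(unname(summary(sf)$table["median"]), survMedian(km))
})

test_that("log-rank statistic matches the hand computation and is symmetric", {
  # A = {1,2} events, B = {3,4} events: O-E = 2 - 5/6, V = 1/4 + 2/9
  res <- logrankTest(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(res@statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-12)
  expect_equal(res@statistic, 2.882353, tolerance = 1e-6)

  same <- logrankTest(c(1, 3, 5), c(1, 0, 1), c(1, 3, 5), c(1, 0, 1))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  set.seed(4)
  tA <- rexp(30, 0.1); tB <- rexp(25, 0.2)
  eA <- rbinom(30, 1, 0.8); eB <- rbinom(25, 1, 0.8)
  ab <- logrankTest(tA, eA, tB, eB)
  ba <- logrankTest(tB, eB, tA, eA)
  expect_equal(ab@statistic, ba@statistic, tolerance = 1e-12)
  expect_equal(ab@pValue, ba@pValue, tolerance = 1e-12)

  noEvents <- logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true("degenerate" %in% noEvents@flags)
})

test_that("log-rank chi-square agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(6)
  for (i in 1:10) {
    tA <- rexp(40, 0.05); tB <- rexp(35, 0.09)
    cA <- rexp(40, 0.02); cB <- rexp(35, 0.02)
    oA <- pmin(tA, cA); eA <- as.integer(tA <= cA)
    oB <- pmin(tB, cB); eB <- as.integer(tB <= cB)
    mine <- logrankTest(oA, eA, oB, eB)
    grp <- c(rep(1, 40), rep(2, 35))
    sd <- survival::survdiff(survival::Surv(c(oA, oB), c(eA, eB)) ~ grp)
    expect_equal(mine@statistic, unname(sd$chisq), tolerance = 1e-9)
  }
})

test_that("rank-sum exact p on canonical splits", {
  res <- ranksumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res@pValue, 0.1, tolerance = 1e-12)   # 2 of C(6,3)=20 splits
  # identical samples: mid-ranks make U its null mean, p = 1
  res <- ranksumTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res@pValue, 1)
  # all values equal across groups: degenerate flag
  res <- ranksumTest(c(2, 2), c(2, 2, 2))
  expect_equal(res@pValue, 1)
  expect_true("degenerate" %in% res@flags)
})

test_that("exact rank-sum p equals brute-force enumeration for nA+nB <= 8", {
  set.seed(7)
  for (i in 1:40) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    vals <- sample(1000, nA + nB)      # distinct -> no ties
    a <- vals[seq_len(nA)]; b <- vals[-seq_len(nA)]
    expect_equal(ranksumTest(a, b)@pValue, bruteRanksumP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum agrees with stats::wilcox.test on both code paths", {
  set.seed(8)
  # exact path
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(ranksumTest(a, b)@pValue,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # tie-corrected normal approximation with continuity correction
  for (i in 1:10) {
    a <- sample(1:8, 25, replace = TRUE); b <- sample(2:9, 30, replace = TRUE)
    expect_equal(ranksumTest(a, b)@pValue,
                 suppressWarnings(wilcox.test(a, b, correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("Gehan-Wilcoxon test: symmetry, single-event formula, rank-sum kinship", {
  same <- gehanWilcoxonTest(c(1, 2, 4), c(1, 1, 0), c(1, 2, 4), c(1, 1, 0))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  # single event overall: one term with w = n_1 = 2, U = 2*(1 - 1/2) = 1,
  # V = 4 * 1 * (1/2)(1/2) * 1 = 1 -> chi-square = 1
  res <- gehanWilcoxonTest(1, 1, 2, 0)
  expect_equal(res@statistic, 1, tolerance = 1e-12)
  expect_equal(res@pValue, pchisq(1, 1, lower.tail = FALSE))

  # without censoring (no ties) the Gehan statistic is the centred
  # Mann-Whitney U up to sign and a factor 2; only the permutation vs
  # rank-sum variance estimators make the p-values differ slightly
  set.seed(9)
  a <- rexp(40, 0.08); b <- rexp(40, 0.16)
  tt <- c(a, b); gA <- c(rep(TRUE, 40), rep(FALSE, 40))
  Ug <- sum(vapply(sort(tt), function(t) {
    atRisk <- tt >= t
    sum(atRisk) * ((t %in% a) - sum(atRisk & gA) / sum(atRisk))
  }, numeric(1)))
  Umw <- sum(rank(tt)[1:40]) - 40 * 41 / 2
  expect_equal(abs(Ug), 2 * abs(Umw - 40 * 40 / 2), tolerance = 1e-9)
  pG <- gehanWilcoxonTest(a, rep(1, 40), b, rep(1, 40))@pValue
  pR <- ranksumTest(a, b)@pValue
  expect_lt(abs(log10(pG) - log10(pR)), 0.2)
})

test_that("compareSurvival dispatches tests on a clinical table", {
  clin <- tinyClinical()
  low <- paste0("S", 1:4); high <- paste0("S", 5:8)
  rs <- compareSurvival(clin, low, high, "os", "ranksum")
  expect_equal(rs@pValue, ranksumTest(clin$os_time[1:4], clin$os_time[5:8])@pValue)
  lr <- compareSurvival(clin, low, high, "os", "logrank")
  expect_s4_class(lr, "SurvivalTestResult")
  expect_error(compareSurvival(clin, low, high, "efs"), "efs")
})
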