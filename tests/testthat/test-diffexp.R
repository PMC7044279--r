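test_that("quantile normalization forces a shared column distribution", {
  x <- cbind(a = c(1, 3, 5), b = c(2, 4, 6))
  xn <- quantileNormalize(x)
  expect_equal(unname(xn[, "a"]), c(1.5, 3.5, 5.5))
  expect_equal(unname(xn[, "b"]), c(1.5, 3.5, 5.5))

  same <- cbind(a = c(2, 7, 4), b = c(2, 7, 4))
  expect_equal(quantileNormalize(same), same)

  set.seed(12)
  y <- matrix(rnorm(300), 50, 6)
  yn <- quantileNormalize(y)
  expect_lt(diff(range(colMeans(yn))), 1e-12)
  expect_equal(quantileNormalize(yn), yn, tolerance = 1e-12)  # idempotent

  expect_warning(z <- quantileNormalize(matrix(1:4, 4, 1)), "single-sample")
  expect_equal(z, matrix(1:4, 4, 1))
})

test_that("quantile normalization matches limma and handles ties/missing", {
  skip_if_not_installed("limma")
  set.seed(13)
  y <- matrix(rnorm(400), 80, 5)
  expect_equal(unname(quantileNormalize(y)),
               unname(limma::normalizeQuantiles(y)), tolerance = 1e-12)
  # ties within a column get the mean of the spanned reference values
  yt <- cbind(c(1, 1, 5), c(2, 4, 6))
  ref <- rowMeans(cbind(sort(yt[, 1]), sort(yt[, 2])))
  expect_equal(unname(quantileNormalize(yt)[, 1]),
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  # missing cells restored after normalization
  ym <- matrix(rnorm(60), 20, 3)
  ym[c(3, 25)] <- NA
  expect_identical(which(is.na(quantileNormalize(ym))), c(3L, 25L))
})

test_that("moderation hyperparameters: limits and robustness", {
  expect_true(is.infinite(estimateModeration(rep(0.4, 100), df = 20)@d0))
  expect_warning(p <- estimateModeration(runif(10, 0.5, 1), df = 10),
                 "fewer than 30")
  expect_equal(p@d0, 0)
  # heavy-tailed contamination: finite d0, no crash
  set.seed(14)
  v <- 0.05 * rf(5000, 20, 4)
  v[1:50] <- v[1:50] * 100
  pc <- estimateModeration(v, df = 20)
  expect_true(is.finite(pc@d0) && pc@d0 > 0)
  expect_gt(pc@s0sq, 0)
})

test_that("moderation recovery matches limma::squeezeVar hyperparameters", {
  skip_if_not_installed("limma")
  set.seed(15)
  v <- 0.05 * rf(5000, 30, 5)
  mine <- estimateModeration(v, df = 30)
  ref <- limma::squeezeVar(v, df = 30)
  expect_equal(mine@d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine@s0sq, ref$var.prior, tolerance = 1e-6)
})

test_that("moderated t with d0 = 0 is the classical pooled t", {
  set.seed(16)
  x <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:12)))
  low <- sprintf("S%02d", 1:6); high <- sprintf("S%02d", 7:12)
  res <- moderatedTTest(x, low, high,
                        params = methods::new("ModerationParams", d0 = 0, s0sq = 1))
  for (i in c(1, 17, 50)) {
    ref <- brutePooledT(x[i, low], x[i, high])
    expect_equal(res$t_moderated[i], ref$t, tolerance = 1e-12)
    expect_equal(res$p_value[i], ref$p, tolerance = 1e-12)
  }
  expect_equal(res$log2fc, res$mean_high - res$mean_low, tolerance = 0)
})

test_that("moderated t with infinite d0 uses the prior variance everywhere", {
  set.seed(17)
  x <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(paste0("P", 1:20), paste0("S", 1:10)))
  low <- paste0("S", 1:5); high <- paste0("S", 6:10)
  res <- moderatedTTest(x, low, high,
                        params = methods::new("ModerationParams", d0 = Inf, s0sq = 0.25))
  expect_true(all(res$posterior_s2 == 0.25))
  expect_equal(res$t_moderated,
               (res$mean_high - res$mean_low) / sqrt(0.25 * (1 / 5 + 1 / 5)),
               tolerance = 1e-12)
})

test_that("moderated t agrees with limma's eBayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(18)
  # heterogeneous per-probe variances so the prior df is finite and the
  # whole moderation path (not just its limit) is exercised
  sigma <- sqrt(4 * 0.3 / rchisq(200, 4))
  x <- matrix(rnorm(200 * 16, sd = rep(sigma, 16)), 200, 16,
              dimnames = list(sprintf("P%03d", 1:200), sprintf("S%02d", 1:16)))
  low <- sprintf("S%02d", 1:8); high <- sprintf("S%02d", 9:16)
  design <- cbind(Intercept = 1, high = rep(c(0, 1), each = 8))
  fit <- limma::eBayes(limma::lmFit(x, design))
  mine <- moderatedTTest(x, low, high)
  expect_equal(mine$t_moderated, fit$t[, "high"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(mine$p_value, fit$p.value[, "high"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("BH adjustment: worked example and brute-force equivalence", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_identical(bhAdjust(numeric()), numeric())
  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bruteBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("differential gene selection applies the fold-change and q cuts", {
  rec <- data.frame(probe_id = c("up", "weak", "down", "null"),
                    log2fc = c(1.2, 0.8, -2.5, 0.1),
                    p_adjusted = c(0.01, 0.001, 0.04, 0.9))
  sel <- selectDEGenes(rec, fcCut = 1, qCut = 0.05)
  expect_identical(sel$up_in_high, "up")
  expect_identical(sel$down_in_high, "down")
  sel15 <- selectDEGenes(rec, fcCut = 1.5, qCut = 0.05)
  expect_length(sel15$up_in_high, 0L)
  expect_identical(sel15$down_in_high, "down")
})

test_that("FDR is controlled under a global null", {
  set.seed(20)
  x <- matrix(rnorm(2000 * 12), 2000, 12,
              dimnames = list(sprintf("P%04d", 1:2000), sprintf("S%02d", 1:12)))
  res <- moderatedTTest(x, sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  expect_lte(mean(res$p_adjusted < 0.05), 0.05)
})
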