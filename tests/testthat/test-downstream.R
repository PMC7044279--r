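test_that("patient clustering on correlation distance", {
  set.seed(23)
  base <- rnorm(20)
  x <- cbind(A = base + rnorm(20, sd = 0.01), B = base + rnorm(20, sd = 0.01),
             C = rnorm(20))
  x <- rbind(x, x)  # 40 genes
  pc <- clusterPatients(x)
  hc <- pc$hclust
  # the two near-identical samples merge first, at near-zero height
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("A", "B"))
  expect_lt(hc$height[1], 0.01)
  expect_false(is.unsorted(hc$height))  # complete linkage heights

  bad <- x; bad[, "C"] <- 3
  expect_error(clusterPatients(bad), "'C'")
})

test_that("planted two-group structure is recovered by cutting the tree", {
  set.seed(24)
  nG <- 50L
  grp <- rep(c(0, 1), each = 15)
  # symmetric group offsets around a shared baseline: within-group
  # correlation ~ +0.5, between-group ~ -0.5
  x <- matrix(rnorm(nG * 30, sd = 1), nG, 30) +
    outer(rnorm(nG, sd = 2), grp - 0.5)
  colnames(x) <- paste0(ifelse(grp == 1, "hi", "lo"), 1:30)
  rownames(x) <- paste0("g", 1:nG)
  pc <- clusterPatients(x)
  cut <- cutree(pc$hclust, k = 2)
  agree <- max(mean((cut == 1) == (grp == 0)), mean((cut == 1) == (grp == 1)))
  expect_gte(agree, 0.9)
  # correlation distance is invariant to per-sample positive affine maps
  scale <- runif(30, 0.5, 3); shift <- rnorm(30, sd = 4)
  x2 <- sweep(sweep(x, 2, scale, "*"), 2, shift, "+")
  pc2 <- clusterPatients(x2)
  expect_equal(pc$hclust$merge, pc2$hclust$merge)
  expect_equal(pc$hclust$height, pc2$hclust$height, tolerance = 1e-9)
})

test_that("gene clustering on z-scored Euclidean distance", {
  set.seed(25)
  n <- 16L
  g1 <- rnorm(n)
  x <- rbind(g1 = g1, g2 = 3 * g1 + 7, neg = -g1, other = rnorm(n))
  colnames(x) <- paste0("S", 1:n)
  gc <- clusterGenes(x)
  # affine transforms have identical z-scores: first merge at height 0
  first <- sort(gc$hclust$labels[-gc$hclust$merge[1, ]])
  expect_identical(first, c("g1", "g2"))
  expect_equal(gc$hclust$height[1], 0, tolerance = 1e-12)
  # a gene and its negation sit at distance 2*sqrt(n-1) after sample-sd
  # z-scoring (z vectors have squared norm n-1)
  d <- dist(gc$zscores)
  expect_equal(as.matrix(d)["g1", "neg"], 2 * sqrt(n - 1), tolerance = 1e-12)

  expect_error(clusterGenes(rbind(a = rep(1, 5), b = rnorm(5))), "'a'")
})

test_that("three-gene agglomeration follows hand-computed distances", {
  # construct z-score-identical triangles with known pairwise distances:
  # d(a,b) < d(a,c) < d(b,c) -> (a,b) merge first, c joins at d(b,c)
  x <- rbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3.5), c = c(3, 2, 1, 0))
  colnames(x) <- paste0("S", 1:4)
  z <- t(scale(t(x)))
  D <- as.matrix(dist(z))
  gc <- clusterGenes(x)
  expect_identical(sort(gc$hclust$labels[-gc$hclust$merge[1, ]]), c("a", "b"))
  expect_equal(gc$hclust$height[1], D["a", "b"], tolerance = 1e-12)
  expect_equal(gc$hclust$height[2], max(D["a", "c"], D["b", "c"]),
               tolerance = 1e-12)  # complete linkage
})

test_that("dendrograms serialize to Newick with merge heights", {
  x <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("S", 1:10)))
  gc <- clusterGenes(x)
  nk <- dendrogramNewick(gc$hclust)
  expect_match(nk$newick, "^\\(.*\\);$")
  expect_setequal(nk$leafOrder, rownames(x))
  tr <- ape::read.tree(text = nk$newick)
  expect_setequal(tr$tip.label, rownames(x))
})

test_that("signal-to-noise scores: formula, symmetry, antisymmetry", {
  set.seed(26)
  x <- rbind(sig = c(rnorm(10, 0, 1), rnorm(10, 2, 1)),
             flat = rep(c(1.0, 1.1), 10))
  x <- rbind(x, matrix(rnorm(40), 2, 20,
                       dimnames = list(c("n1", "n2"), NULL)))
  colnames(x) <- paste0("S", 1:20)
  low <- paste0("S", 1:10); high <- paste0("S", 11:20)
  rk <- signalToNoiseRank(x, low, high)
  sig <- rk[rk$gene == "sig", ]
  mH <- mean(x["sig", high]); mL <- mean(x["sig", low])
  sdH <- max(sd(x["sig", high]), 0.2 * abs(mH), 0.2)
  sdL <- max(sd(x["sig", low]), 0.2 * abs(mL), 0.2)
  expect_equal(sig$score, (mH - mL) / (sdH + sdL), tolerance = 1e-12)
  # identical group distributions score zero
  expect_equal(rk$score[rk$gene == "flat"], 0)
  # swapping labels negates all scores and reverses the ranking
  rk2 <- signalToNoiseRank(x, high, low)
  expect_equal(rk2$score[match(rk$gene, rk2$gene)], -rk$score, tolerance = 1e-12)
  expect_identical(rk2$gene, rev(rk$gene))
})

test_that("enrichment score matches the brute-force running sum", {
  # single-member set ranked first reaches ES = 1 before any miss
  rk <- data.frame(gene = paste0("g", 1:10), score = 10:1)
  expect_equal(enrichmentScore(rk, "g1")$es, 1.0)
  expect_error(enrichmentScore(rk, "absent"), "no member")
  expect_error(enrichmentScore(rk, paste0("g", 1:10)), "entire")

  set.seed(27)
  for (i in 1:20) {
    N <- sample(20:100, 1)
    genes <- paste0("g", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(genes, sample(2:10, 1))
    rk <- data.frame(gene = genes, score = scores)
    mine <- enrichmentScore(rk, set)
    expect_equal(mine$es, bruteES(genes, scores, set), tolerance = 1e-12)
    # reversing the ranking with negated scores negates the ES
    rev <- data.frame(gene = base::rev(genes), score = -base::rev(scores))
    expect_equal(enrichmentScore(rev, set)$es, -mine$es, tolerance = 1e-12)
  }
})

test_that("GSEA permutation p: determinism, floor, null behaviour", {
  set.seed(28)
  x <- matrix(rnorm(200 * 24), 200, 24,
              dimnames = list(paste0("g", 1:200), paste0("S", 1:24)))
  low <- paste0("S", 1:12); high <- paste0("S", 13:24)
  set <- paste0("g", 1:10)
  g1 <- gseaPermutation(x, low, high, set, nPerm = 200L, seed = 5L)
  g2 <- gseaPermutation(x, low, high, set, nPerm = 200L, seed = 5L)
  expect_equal(g1, g2)
  expect_gte(g1@pPerm, 1 / 201)
  # on null data permutation p-values are approximately uniform:
  # Kolmogorov distance from Uniform(0,1) below 0.1 over 200 repetitions
  ps <- vapply(1:200, function(i) {
    gseaPermutation(x, low, high, paste0("g", sample(200, 8)),
                    nPerm = 100L, seed = i)@pPerm
  }, numeric(1))
  grid <- seq(0, 1, by = 0.01)
  ksDist <- max(abs(vapply(grid, function(q) mean(ps <= q), numeric(1)) - grid))
  expect_lt(ksDist, 0.1)
  expect_gte(mean(ps > 0.05), 0.85)
})

test_that("probe-probe correlation: identities and null bound", {
  set.seed(29)
  x <- matrix(rnorm(3 * 500), 3, 500,
              dimnames = list(c("a", "b", "c"), paste0("S", 1:500)))
  x["b", ] <- -x["a", ]
  expect_equal(correlateProbes(x, "a", "a")$r, 1)
  expect_equal(correlateProbes(x, "a", "b")$r, -1)
  indep <- correlateProbes(x, "a", "c")
  expect_lt(abs(indep$r), 0.12)   # ~2.5/sqrt(n) null envelope
  expect_gt(indep$p, 0.001)
  expect_error(correlateProbes(x[, 1:2], "a", "c"), "3 shared")
})
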