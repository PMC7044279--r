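#' Hierarchical clustering of patients on correlation distance
#'
#' Pairwise Pearson correlation r between patient expression profiles
#' (columns), distance d = 1 - r, complete-linkage agglomeration. The
#' clustering is invariant to per-gene affine rescaling of the matrix.
#' A Euclidean-distance-on-correlation-rows variant is available since the
#' two readings of "correlation + Euclidean" clustering cannot be told
#' apart from a figure; the choice is recorded on the result.
#'
#' @param x Numeric gene-by-sample matrix, typically restricted to the
#'   differential genes (>= 2 genes, >= 3 samples).
#' @param distance \code{"pearson"} (d = 1 - r, default) or
#'   \code{"euclidean-r"} (Euclidean distance between correlation rows).
#' @return list with elements \code{hclust} (a \code{stats::hclust} tree),
#'   \code{correlation} (the sample correlation matrix) and
#'   \code{distance} (the distance name).
#' @export
clusterPatients <- function(x, distance = c("pearson", "euclidean-r")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (nrow(x) < 2L) stop("need at least 2 genes")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance sample '%s': correlation undefined",
                 colnames(x)[which(sds == 0)[1L]]))
  r <- cor(x)
  d <- if (distance == "pearson") stats::as.dist(1 - r) else dist(r)
  hc <- hclust(d, method = "complete")
  list(hclust = hc, correlation = r, distance = distance)
}

#' Hierarchical clustering of genes on z-scored profiles
#'
#' Each gene is z-scored across samples (mean 0, unit sample sd), then
#' genes are agglomerated by complete linkage on Euclidean distance.
#'
#' @param x Numeric gene-by-sample matrix (>= 2 genes; every gene
#'   non-constant).
#' @return list with \code{hclust} and the z-scored matrix \code{zscores}.
#' @export
clusterGenes <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("need at least 2 genes")
  sds <- apply(x, 1L, sd)
  if (any(sds == 0))
    stop(sprintf("constant gene '%s': z-score undefined",
                 rownames(x)[which(sds == 0)[1L]]))
  z <- t(scale(t(x)))
  hc <- hclust(dist(z), method = "complete")
  list(hclust = hc, zscores = z)
}

#' Serialize an hclust tree as a Newick string
#'
#' Merge heights become branch lengths, so the dendrogram can be consumed
#' by any phylogenetics viewer; the leaf order is also returned for
#' heatmap reproduction.
#'
#' @param hc A \code{stats::hclust} object.
#' @param path Optional output path; when given the Newick string is
#'   written there.
#' @return list(newick, leafOrder); invisibly when \code{path} is given.
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  out <- list(newick = nwk, leafOrder = hc$labels[hc$order])
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(out))
  }
  out
}

#' Signal-to-noise gene ranking between expresser groups
#'
#' Per gene, s2n = (mean_high - mean_low) / (sd_high + sd_low), the GSEA
#' ranking metric, with each group sd floored at max(0.2 * |group mean|,
#' 0.2) so near-constant genes cannot dominate and division by zero cannot
#' occur. Genes are returned sorted by descending score; swapping the group
#' labels negates every score and reverses the ranking.
#'
#' @param x Numeric gene-by-sample matrix.
#' @param lowIds,highIds Sample-id vectors, each of size >= 3.
#' @return data.frame(gene, score) sorted by descending score.
#' @export
signalToNoiseRank <- function(x, lowIds, highIds) {
  stopifnot(is.matrix(x))
  if (length(lowIds) < 3L || length(highIds) < 3L)
    stop("both groups need at least 3 samples")
  if (!all(c(lowIds, highIds) %in% colnames(x)))
    stop("group sample ids missing from matrix columns")
  xL <- x[, lowIds, drop = FALSE]; xH <- x[, highIds, drop = FALSE]
  mL <- rowMeans(xL); mH <- rowMeans(xH)
  rowSd <- function(m, mu) {
    n <- ncol(m)
    sqrt(pmax(0, (rowSums(m * m) - n * mu^2) / (n - 1)))
  }
  sdL <- rowSd(xL, mL); sdH <- rowSd(xH, mH)
  sdL <- pmax(sdL, pmax(0.2 * abs(mL), 0.2))
  sdH <- pmax(sdH, pmax(0.2 * abs(mH), 0.2))
  score <- (mH - mL) / (sdH + sdL)
  out <- data.frame(gene = rownames(x), score = unname(score))
  out[order(-out$score), , drop = FALSE]
}

#' GSEA enrichment score along a ranked gene list
#'
#' Weighted Kolmogorov-Smirnov running sum with weight exponent 1: walking
#' down the ranking, a gene-set member ("hit") adds |score| / sum of
#' |score| over in-list members, a non-member subtracts 1 / (N - N_hit).
#' The enrichment score is the running-sum value of maximal absolute
#' deviation (signed); the leading edge contains the hits at or before the
#' peak for a positive ES (at or after, for a negative ES).
#'
#' @param ranking data.frame(gene, score) sorted by descending score (from
#'   \code{\link{signalToNoiseRank}}), or a named numeric score vector in
#'   ranked order.
#' @param geneSet Character vector of member identifiers; must share at
#'   least one gene with the ranking and must not cover the whole list.
#' @return list(es, runningSum, leadingEdge).
#' @export
enrichmentScore <- function(ranking, geneSet) {
  if (is.data.frame(ranking)) {
    genes <- ranking$gene; scores <- ranking$score
  } else {
    genes <- names(ranking); scores <- unname(ranking)
  }
  N <- length(genes)
  hit <- genes %in% geneSet
  nHit <- sum(hit)
  if (nHit == 0L) stop("gene set has no member in the ranked list")
  if (nHit == N) stop("gene set covers the entire ranked list")
  sumHit <- sum(abs(scores[hit]))
  inc <- ifelse(hit,
                if (sumHit > 0) abs(scores) / sumHit else 1 / nHit,
                -1 / (N - nHit))
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  es <- running[peak]
  leading <- if (es >= 0) genes[hit & seq_len(N) <= peak]
             else genes[hit & seq_len(N) >= peak]
  list(es = es, runningSum = running, leadingEdge = leading)
}

#' GSEA with phenotype-label permutation
#'
#' Computes the observed enrichment score from the signal-to-noise ranking
#' of high vs low expressers, then permutes the group labels \code{nPerm}
#' times under a fixed seed, re-ranking and re-scoring each time.
#' p_perm = (1 + #permutations with |ES| >= |ES_obs|) / (1 + nPerm); the
#' normalized score NES divides ES_obs by the mean |ES| of the same-sign
#' permutations. A degenerate observed ES of 0 reports p = 1.
#'
#' @param x Numeric gene-by-sample matrix.
#' @param lowIds,highIds Sample-id vectors (>= 3 each).
#' @param geneSet Character vector of member identifiers.
#' @param setName Name recorded on the result.
#' @param nPerm Number of permutations (>= 100; default 1000).
#' @param seed Integer RNG seed.
#' @return A \linkS4class{GSEAResult}.
#' @export
gseaPermutation <- function(x, lowIds, highIds, geneSet,
                            setName = "gene_set", nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  obsRank <- signalToNoiseRank(x, lowIds, highIds)
  obs <- enrichmentScore(obsRank, geneSet)
  nL <- length(lowIds)
  all <- c(lowIds, highIds)
  esPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    perm <- sample(all)
    enrichmentScore(signalToNoiseRank(x, perm[seq_len(nL)],
                                      perm[-seq_len(nL)]), geneSet)$es
  }, numeric(1L)))
  if (obs$es == 0) {
    p <- 1; nes <- 0
  } else {
    p <- (1 + sum(abs(esPerm) >= abs(obs$es))) / (1 + nPerm)
    sameSign <- esPerm[sign(esPerm) == sign(obs$es)]
    nes <- if (length(sameSign)) obs$es / mean(abs(sameSign)) else NA_real_
  }
  methods::new("GSEAResult", setName = setName, es = obs$es, nes = nes,
               pPerm = p, nPermutations = as.integer(nPerm),
               leadingEdge = obs$leadingEdge, runningSum = obs$runningSum,
               seed = as.integer(seed))
}

#' Pearson correlation between two probes
#'
#' Correlation across the samples where both probes are non-missing, with
#' the two-sided p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param x Numeric probe-by-sample matrix.
#' @param probeA,probeB Probe identifiers (rows of \code{x}).
#' @return list(r, p, n).
#' @export
correlateProbes <- function(x, probeA, probeB) {
  stopifnot(is.matrix(x))
  if (!all(c(probeA, probeB) %in% rownames(x)))
    stop("probe id(s) missing from matrix")
  a <- x[probeA, ]; b <- x[probeB, ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 shared non-missing samples")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) stop("constant probe: correlation undefined")
  ct <- cor.test(a[ok], b[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
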