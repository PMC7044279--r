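# Independent brute-force oracles, deliberately written as naive
# re-derivations so they share no code path with the package.

# Two-sided rank-sum p by full enumeration of label assignments.
# Assumes no ties, where "distance from the null mean" tails coincide with
# the 2*min(tail) convention (the null rank-sum distribution is symmetric).
bruteRanksumP <- function(a, b) {
  n <- length(a) + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  mu <- length(a) * (n + 1) / 2
  combs <- utils::combn(n, length(a))
  stats <- apply(combs, 2L, function(ix) sum(r[ix]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by direct hypergeometric enumeration with
# binomial coefficients (no dhyper).
bruteFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  prob <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pObs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  sum(prob[prob <= pObs * (1 + 1e-7)])
}

# Literal BH step-up: sort ascending, p_(i) * m / i, running min from the
# top, cap at 1, restore input order.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Literal weighted-KS running sum (weight exponent 1) via an explicit loop.
bruteES <- function(genes, scores, set) {
  N <- length(genes)
  hit <- genes %in% set
  sumHit <- sum(abs(scores[hit]))
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) abs(scores[i]) / sumHit else -1 / (N - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Classical pooled two-sample t (the d0 = 0 limit of the moderated test).
brutePooledT <- function(xl, xh) {
  nL <- length(xl); nH <- length(xh)
  s2 <- (sum((xl - mean(xl))^2) + sum((xh - mean(xh))^2)) / (nL + nH - 2)
  tt <- (mean(xh) - mean(xl)) / sqrt(s2 * (1 / nL + 1 / nH))
  list(t = tt, p = 2 * stats::pt(abs(tt), df = nL + nH - 2, lower.tail = FALSE))
}
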