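# Independent brute-force oracles, coded from first principles and kept
# separate from the package's implementation paths.

# ARI by direct pair counting: classify every pair of items as co-clustered
# or not in each labeling, then apply the pair-count form of the adjusted
# index.
oracleARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

# Silhouette widths by the textbook definition: a(i) mean distance to own
# cluster, b(i) min over other clusters of mean distance; singletons get 0.
oracleSilhouette <- function(labels, d) {
  n <- length(labels)
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) { out[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(d[i, labels == k]), numeric(1)))
    out[i] <- (b - a) / max(a, b)
  }
  out
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n, nx) group assignments of the pooled values.
oracleWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U of x
  combs <- utils::combn(length(pooled), nx)
  u <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u <= obs), mean(u >= obs)))
}

# Two-group log-rank chi-square from the score statistic: hypergeometric
# expected deaths and variance at each distinct event time.
oracleLogrank2 <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  stopifnot(length(unique(g)) == 2)
  ts <- sort(unique(times[events == 1]))
  U <- 0; V <- 0
  for (t in ts) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    e1 <- d * n1 / n
    U <- U + (d1 - e1)
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# TMM factor ratio of two samples by direct evaluation of the
# trimmed-weighted-mean-of-M-values formula: genes nonzero in both samples;
# M = library-size-adjusted log2 ratio, A = average log2 abundance;
# double trim (30% on M, 5% on A) by ranks; weights = inverse asymptotic
# binomial variance.
oracleTMMPair <- function(yTest, yRef) {
  nT <- sum(yTest); nR <- sum(yRef)
  keep <- yTest > 0 & yRef > 0
  yT <- yTest[keep]; yR <- yRef[keep]
  M <- log2((yT / nT) / (yR / nR))
  A <- 0.5 * log2((yT / nT) * (yR / nR))
  w <- (nT - yT) / (nT * yT) + (nR - yR) / (nR * yR)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# Benjamini-Hochberg step-up by the direct min-over-larger-ranks formula.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "first")
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  runmin <- rev(cummin(rev(sorted)))
  pmin(1, runmin[r])
}
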