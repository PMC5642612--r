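# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities through different code paths
# (enumeration, base-R model fits) than the package implementation.

# tiny labeled cohort: 4 clusters, nPer samples each, nGenes null genes
toyCohort <- function(nPer = 3, nGenes = 10, seed = 1, noise = 1,
                      baseline = 5) {
  set.seed(seed)
  labels <- rep(c("I", "II", "III", "IV"), each = nPer)
  m <- matrix(rnorm(nGenes * length(labels), baseline, noise), nGenes,
              dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_along(labels))))
  ImmuneCohort(m, scale = "log2", cluster = labels)
}

# exhaustive binomial tail by direct pmf summation (no pbinom)
enumBinomTail <- function(k, n, p, direction) {
  pmf <- vapply(0:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
                numeric(1))
  if (direction == "+") sum(pmf[(k + 1):(n + 1)]) else sum(pmf[1:(k + 1)])
}

# brute-force dual-centroid assignment: enumerate all 8 distances
bruteAssign <- function(s, main, alt, clusters = c("I", "II", "III", "IV")) {
  dm <- apply(main, 2, function(cv) sqrt(sum((s - cv)^2)))
  da <- apply(alt, 2, function(cv) sqrt(sum((s - cv)^2)))
  best <- which(dm == min(dm))
  if (length(best) != 1) return("UNCLASSIFIED")
  if (dm[best] < da[best]) clusters[best] else "UNCLASSIFIED"
}

# independent implementations of the five one-vs-rest discriminators,
# computed gene by gene with base-R model fits where possible
oracleScores <- function(X, y) {
  t(apply(X, 1, function(x) {
    x1 <- x[y]; x0 <- x[!y]
    tt <- if (sd(x) == 0) 0 else
      abs(unname(t.test(x1, x0, var.equal = FALSE)$statistic))
    W <- suppressWarnings(wilcox.test(x1, x0, exact = FALSE)$statistic)
    aucs <- if (sd(x) == 0) 0 else
      abs(unname(W) / (length(x1) * length(x0)) - 0.5)
    snr <- if (sd(x) == 0) 0 else {
      den <- sd(x1) + sd(x0)
      num <- abs(mean(x1) - mean(x0))
      if (den == 0) { if (num > 0) Inf else 0 } else num / den
    }
    md <- abs(mean(x1) - mean(x0))
    b <- x > median(x)
    mi <- if (sd(x) == 0) 0 else {
      tab <- table(factor(b, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
      pj <- tab / sum(tab)
      plogp <- function(q) sum(ifelse(q > 0, q * log(q), 0))
      plogp(rowSums(pj)) * -1 + plogp(colSums(pj)) * -1 - (-plogp(pj))
    }
    c(t = tt, auc = aucs, snr = snr, meandiff = md, mi = mi)
  }))
}
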