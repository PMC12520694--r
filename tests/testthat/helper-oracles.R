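# Independent brute-force oracles. These deliberately re-derive each
# statistic with explicit loops, separate from the package implementations.

# Running-sum enrichment score by direct enumeration over positions.
# Ranking: decreasing expression, ties broken by ascending gene id; tied
# expression values share the average of their rank weights.
bruteSsgsea <- function(expr, geneIds, setGenes, alpha) {
  N <- length(expr)
  ord <- order(-expr, geneIds)
  w <- numeric(N)
  for (i in seq_len(N)) {
    same <- which(expr[ord] == expr[ord][i])
    w[i] <- mean(N - same + 1)
  }
  wa <- w^alpha
  inSet <- geneIds[ord] %in% setGenes
  es <- 0
  denomIn <- sum(wa[inSet])
  nOut <- N - sum(inSet)
  for (i in seq_len(N)) {
    pin <- sum(wa[seq_len(i)][inSet[seq_len(i)]]) / denomIn
    pout <- sum(!inSet[seq_len(i)]) / nOut
    es <- es + (pin - pout)
  }
  es
}

# Two-sided rank-sum p by full enumeration over all C(n, n1) group
# assignments, using |U - E[U]| as the extremity measure.
enumRankSumP <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  n <- length(z)
  r <- rank(z)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mU <- n1 * (n - n1) / 2
  obs <- abs(uOf(seq_len(n1)) - mU)
  combs <- utils::combn(n, n1)
  hits <- 0L
  for (j in seq_len(ncol(combs)))
    if (abs(uOf(combs[, j]) - mU) >= obs - 1e-12) hits <- hits + 1L
  hits / ncol(combs)
}

# AUROC by explicit enumeration of positive-negative pairs, ties 0.5.
pairwiseAuroc <- function(truth, scores) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# Best log-likelihood of a 2-component Gaussian mixture over a coarse
# parameter grid (a floor the EM solution must reach or beat).
gridGmmLL <- function(v, mu1Grid, mu2Grid, sdGrid, wGrid) {
  best <- -Inf
  for (m1 in mu1Grid) for (m2 in mu2Grid) for (s in sdGrid)
    for (w in wGrid) {
      ll <- sum(log(w * dnorm(v, m1, s) + (1 - w) * dnorm(v, m2, s)))
      if (ll > best) best <- ll
    }
  best
}
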