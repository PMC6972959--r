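# Independent oracles used across the suite.

# brute-force MHS pair count: enumerate all unordered pairs
bruteForcePairs <- function(mothers) {
  n <- length(mothers)
  cnt <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (mothers[i] == mothers[j]) cnt <- cnt + 1L
  cnt
}

# exact expectation of g(H) under H ~ Binomial(nPair, 1/ne)
binomExpect <- function(g, ne, nPair) {
  h <- 0:nPair
  sum(stats::dbinom(h, nPair, 1 / ne) * g(h))
}

# leave-one-history-out jackknife SE of a statistic of a replicate table
jackknifeSE <- function(replicates, stat) {
  hs <- unique(replicates$history)
  vals <- vapply(hs, function(i) stat(replicates[replicates$history != i, ]),
                 0.0)
  m <- length(hs)
  sqrt((m - 1) / m * sum((vals - mean(vals))^2))
}

# SE of a pooled mean from history-level means (clustered observations)
historySE <- function(replicates, col) {
  hm <- tapply(replicates[[col]], replicates$history, mean)
  stats::sd(hm) / sqrt(length(hm))
}
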