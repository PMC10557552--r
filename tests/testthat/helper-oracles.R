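# Independent oracles, kept deliberately naive.

# Spearman via the classical tie-free difference formula.
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Spearman as Pearson correlation of the rank vectors.
oracle_spearman_pearson <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Kendall by full O(n^2) pair enumeration of sign products.
oracle_kendall_pairs <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  2 * s / (n * (n - 1))
}

# Rank autocorrelation by direct summation with full-sample denominator.
oracle_rank_autocorr <- function(v, h) {
  r <- rank(v, ties.method = "average")
  rb <- mean(r)
  sum((r[1:(length(v) - h)] - rb) * (r[(1 + h):length(v)] - rb)) /
    sum((r - rb)^2)
}
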