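# Independent oracles, kept free of the package's own code paths.

# Two-sided Fisher p by brute-force enumeration: probabilities of all 2x2
# tables with the observed margins computed from binomial coefficients,
# summing those not exceeding the observed table's probability (standard
# 1 + 1e-7 relative tie tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  sum(p[p <= p[a - lo + 1L] * (1 + 1e-7)])
}

# Hypergeometric upper tail P[X >= k] by direct pmf summation.
oracle_hyper_upper <- function(n_A, n_B, k, N) {
  hi <- min(n_A, n_B)
  if (k > hi) return(0)
  j <- k:hi
  sum(exp(lchoose(n_B, j) + lchoose(N - n_B, n_A - j) - lchoose(N, n_A)))
}

# toy genome with known block structure: TE - gene - TE - intergenic
toy_genome_seq <- function(n_rep = 3L, seed = 42L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 6000L * n_rep, replace = TRUE,
               prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
}

# small methylome built directly from counts
toy_sample <- function(df, label = "toy") {
  methylome(df, label = label)
}
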