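# Independent oracles used to freeze expected values. These deliberately use
# direct summation / brute-force sampling, never the package's own code paths.

# upper-tail Poisson by direct summation of density terms
oracle_poisson_upper <- function(m, lambda) {
  if (m == 0) return(1)
  1 - sum(exp(-lambda) * lambda^(0:(m - 1)) / factorial(0:(m - 1)))
}

# binomial lower tail P(X < k) by direct summation
oracle_binom_below <- function(k, n, p) {
  if (k <= 0) return(0)
  sum(choose(n, 0:(k - 1)) * p^(0:(k - 1)) * (1 - p)^(n - (0:(k - 1))))
}

# binomial upper tail P(X >= k) by direct summation
oracle_binom_at_least <- function(k, n, p) {
  if (k > n) return(0)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# zero-truncated Poisson pmf at m, by definition
oracle_cond_poisson <- function(m, lambda) {
  exp(-lambda) * lambda^m / factorial(m) / (1 - exp(-lambda))
}

# Rejection-sampling oracle for the screen model: draws per-gene Poisson
# counts for each strain and redraws any strain with no target-region
# mutation. Returns per-target-gene totals for one experiment.
oracle_rejection_experiment <- function(n_strains, n_targets, n_genes, mu) {
  totals <- rep(0L, n_targets)
  nontarget <- rep(0L, n_genes - n_targets)
  for (s in seq_len(n_strains)) {
    repeat {
      counts <- rpois(n_genes, mu)
      if (sum(counts[seq_len(n_targets)]) >= 1L) break
    }
    totals <- totals + counts[seq_len(n_targets)]
    nontarget <- nontarget + counts[-seq_len(n_targets)]
  }
  list(target = totals, nontarget = nontarget)
}

# exhaustive threshold check for the count-based yield rule
oracle_yield <- function(target_counts, nontarget_counts, fdr) {
  m_max <- max(target_counts, nontarget_counts, 0)
  if (m_max < 1) return(0L)
  for (h in 1:m_max) {
    ok <- TRUE
    for (m in h:m_max) {
      nt <- sum(nontarget_counts >= m)
      tg <- sum(target_counts >= m)
      if (nt + tg > 0 && !(nt / (nt + tg) < fdr)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(sum(target_counts >= h))
  }
  0L
}
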