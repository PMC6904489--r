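# Independent oracles used to cross-check the package's own statistics.

# Hypergeometric upper tail by direct enumeration of the probability mass.
oracle_hyper_enum <- function(N, K, n, k) {
  js <- 0:min(K, n)
  mass <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(mass[js >= k])
}

# Exact two-sided Mann-Whitney p from the null U distribution (dwilcox).
oracle_mw_exact <- function(x, y) {
  n <- length(x)
  m <- length(y)
  u <- sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2
  us <- 0:(n * m)
  mass <- stats::dwilcox(us, n, m)
  centre <- n * m / 2
  sum(mass[abs(us - centre) >= abs(u - centre) - 1e-9])
}

# Small random DE-like table for partition tests.
random_pvals <- function(n) runif(n)

# Minimal hand-made de_result-shaped tibble.
fake_de <- function(gene, log2fc, q, p = q) {
  tibble::tibble(gene = gene, base_mean = 100, log2fc = log2fc,
                 se = 0.1, wald = log2fc / 0.1, p = p, q = q,
                 status = "ok")
}

# Default cohort config scaled down for speed where full size is not needed.
small_config <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 200L, n_signature = 20L, ...)
}
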