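# Independent oracles used across tests; deliberately naive implementations
# that never share code with the package internals they check.

# Step-up Benjamini-Hochberg, written directly from the definition.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Clopper-Pearson bounds by bisecting the exact binomial tail probabilities.
bisect_cp <- function(k, m, level = 0.95, tol = 1e-12) {
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else {
    # largest p with Pr(X >= k | p) <= a/... : solve Pr(X >= k | p) = a
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pbinom(k - 1, m, mid, lower.tail = FALSE) < a) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  high <- if (k == m) 1 else {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pbinom(k, m, mid) > a) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(low = low, high = high)
}

# Monte-Carlo BLN pmf: draws from the generative definition.
mc_bln_pmf <- function(n, mu, sigma, draws = 1e5) {
  x <- rbinom(draws, n, plogis(rnorm(draws, mu, sigma)))
  tabulate(x + 1L, n + 1L) / draws
}

# Small simulated cohort used by several suites.
toy_sim <- function(seed = 42, ...) {
  simulate_population(sim_config(seed = seed, ...))
}
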