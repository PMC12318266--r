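# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# Benjamini-Hochberg step-up, from the definition: sort ascending,
# adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1, original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= q) by exhaustive summation of the pmf
# written out with choose().
hyper_tail_oracle <- function(q, universe, set, module) {
  i <- max(q, 0):min(module, set)
  if (length(i) == 0 || max(q, 0) > min(module, set)) return(0)
  sum(choose(set, i) * choose(universe - set, module - i)) /
    choose(universe, module)
}

# Adjusted Rand index from the contingency table (Hubert & Arabie).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Default marker sets for the simulated panel: the first twenty genes of
# each monotone class, the size of published zonation signatures.
sim_markers <- function() {
  list(pericentral = sprintf("PC%03d", 1:20),
       periportal = sprintf("PP%03d", 1:20))
}

# Small lobule simulation reused by several files.
small_lobule <- function(seed = 5, n = 200, ...) {
  simulate_lobule(lobule_sim_config(n_nuclei_per_genotype = n, seed = seed,
                                    ...))
}
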