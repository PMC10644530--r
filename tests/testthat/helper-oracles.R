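# Independent oracles used across the suite. These deliberately use
# different algorithms from the package code they check.

# Brute-force last-common-ancestor finder: build every individual's
# full root-to-leaf ancestor path, then take the latest time at which
# all paths pass through a single individual.
oracle_lca <- function(parents) {
  T <- nrow(parents); N <- ncol(parents)
  # path[t + 1, j] = ancestor at time t of individual j of the final step
  path <- matrix(NA_integer_, T + 1, N)
  path[T + 1, ] <- seq_len(N)
  for (t in T:1) path[t, ] <- parents[t, path[t + 1, ]]
  for (t in T:1) { # latest strictly pre-final time with a single ancestor
    anc <- unique(path[t, ])
    if (length(anc) == 1L)
      return(list(lca_time = t - 1L, lca_index = anc, coalesced = TRUE))
  }
  list(lca_time = 0L, lca_index = NA_integer_, coalesced = FALSE)
}

random_ancestry <- function(N, T) {
  matrix(sample.int(N, N * T, replace = TRUE), nrow = T, ncol = N)
}

# Direct textbook Pearson correlation, written out in full.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small-scale study conditions used by fast tests: same model, reduced
# population and horizon.
small_config <- function(...) {
  sim_config(N = 60, steps = 60, ...)
}
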