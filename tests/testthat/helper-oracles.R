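# Independent oracles used to cross-check the package's own computations.

# Bruvo distance by exhaustive enumeration of allele pairings.
oracle_bruvo_pair <- function(g1, g2, motifs) {
  per_locus <- numeric(0)
  for (j in seq_along(motifs)) {
    a <- g1[j, ]; b <- g2[j, ]
    if (any(is.na(a)) || any(is.na(b))) next
    da <- function(x, y) 1 - 2^(-abs(x - y) / motifs[j])
    best <- Inf
    for (perm in list(1:2, 2:1))
      best <- min(best, mean(c(da(a[1], b[perm[1]]), da(a[2], b[perm[2]]))))
    per_locus <- c(per_locus, best)
  }
  mean(per_locus)
}

# Multivariate normal density, written out from the formula.
oracle_mvn_density <- function(x, mu, S) {
  k <- length(mu)
  diff <- x - mu
  exp(-0.5 * t(diff) %*% solve(S) %*% diff) /
    sqrt((2 * pi)^k * det(S))
}

# Wilson interval by inverting the score test on a fine grid.
oracle_wilson_grid <- function(successes, n, z = 1.96, step = 1e-6) {
  p_hat <- successes / n
  grid <- seq(step, 1 - step, by = step)
  stat <- abs(p_hat - grid) / sqrt(grid * (1 - grid) / n)
  ok <- grid[stat <= z]
  c(min(ok), max(ok))
}

# Expected heterozygosity by explicit counting.
oracle_he <- function(alleles) {
  tab <- table(alleles)
  p <- as.numeric(tab) / sum(tab)
  1 - sum(p^2)
}

# A small simulated dataset shared across tests.
tiny_sim <- function(seed = 42, ...) {
  simulate_dataset(sim_config(seed = seed, ...))
}
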