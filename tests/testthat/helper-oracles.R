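# Independent oracles and small fixtures used across the suite.

# Brute-force mutual information of a joint count table, in bits:
# sum_ij p_ij log2( p_ij / (p_i. p_.j) ). Written directly from the
# definition, independent of the package's entropy-difference route.
brute_force_mi <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p)
  p_j <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      if (p[i, j] > 0)
        tot <- tot + p[i, j] * log2(p[i, j] / (pi_[i] * p_j[j]))
  tot
}

# Expand a joint count table into paired (s, z) vectors whose quantile
# binning reproduces the table exactly (distinct z value per column).
table_to_samples <- function(tab) {
  s <- rep(rep(seq_len(nrow(tab)), ncol(tab)), as.vector(tab))
  z <- rep(rep(seq_len(ncol(tab)), each = nrow(tab)), as.vector(tab))
  list(s = factor(s), z = as.numeric(z))
}

# Single-species pure death network: A -> 0 at rate k.
death_network <- function(k = 0.1) {
  reaction_network("A", list(
    list(name = "death", reactants = c(A = 1), products = integer(0),
         rate = k)))
}

# Birth-death: 0 -> A at rate b, A -> 0 at rate d; stationary law Poisson(b/d).
birth_death_network <- function(b = 5, d = 0.5) {
  reaction_network("A", list(
    list(name = "birth", reactants = integer(0), products = c(A = 1),
         rate = b),
    list(name = "death", reactants = c(A = 1), products = integer(0),
         rate = d)))
}

# Two null reactions (state never changes): total propensity is constant,
# so inter-event waiting times are iid Exponential((k1 + k2) * A0).
null_event_network <- function(k1 = 0.3, k2 = 0.2) {
  reaction_network("A", list(
    list(name = "n1", reactants = c(A = 1), products = c(A = 1), rate = k1),
    list(name = "n2", reactants = c(A = 1), products = c(A = 1), rate = k2)))
}

# Noise-free synthetic assay with degenerate background: the response is a
# deterministic function of (stimulus, time).
noiseless_config <- function(cells = 1000, times = 5) {
  assay_config(times = times, cells_per_condition = cells,
               background = c(135, 135), amp_cv = 0, ec50_sdlog = 0,
               noise_cv = 0)
}
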