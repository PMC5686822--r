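# Shared tiny fixtures and independent oracles for the test suite.

# Interaction lines for a small hand-checkable bipartite graph.
tiny_lines <- function() {
  c("hsa-miR-A\tG1", "hsa-miR-A\tG2", "hsa-miR-A\tG3",
    "hsa-miR-B\tG2", "hsa-miR-B\tG3", "hsa-miR-B\tG4", "hsa-miR-B\tG5",
    "hsa-miR-C\tG9")
}

tiny_interactions <- function() {
  parse_interactions(tiny_lines(), header = "no", quiet = TRUE)
}

# Random small interaction set (seeded) for property tests.
random_interactions <- function(n_m = 5, n_g = 8, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    hit <- matrix(runif(n_m * n_g) < p, nrow = n_m)
    if (all(rowSums(hit) > 0)) break
  }
  idx <- which(hit, arr.ind = TRUE)
  lines <- paste0("mir-", letters[idx[, 1]], "\tG", idx[, 2])
  parse_interactions(lines, header = "no", quiet = TRUE)
}

# Independent RWR oracle: direct linear solve of the fixed point
# p = gamma (I - (1 - gamma) W')^{-1} p0 with W' built by hand from the
# dense adjacency (transpose of row-normalized).
rwr_linear_solve <- function(adj, p0, gamma) {
  rs <- rowSums(adj)
  Wn <- adj / ifelse(rs == 0, 1, rs)
  Wn[rs == 0, ] <- 0
  op <- t(Wn)
  n <- nrow(adj)
  solve(diag(n) - (1 - gamma) * op, gamma * p0)
}

# Dense adjacency of a network, in transition_matrix node order.
dense_adjacency <- function(net) {
  tm <- transition_matrix(net)
  as.matrix(tm$adj)
}

# Mann-Whitney pair-counting AUC oracle from raw positive/negative
# scores (ties count 1/2).
pair_auc <- function(pos, neg) {
  wins <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(wins)
}

# Brute-force hypergeometric upper tail by enumerating all draws of
# size n from a universe of N with K successes (N <= 12).
hyper_enum <- function(k, K, n, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}
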