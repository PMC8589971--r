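# Independent brute-force oracles used to cross-check the package's
# implementations on small graphs. These deliberately avoid the code paths
# they verify: distances come from Floyd-Warshall on a dense matrix,
# betweenness/closeness from explicit path enumeration over BFS layerings,
# and tau from literal pair counting.

# Dense all-pairs hop distances by Floyd-Warshall (Inf = unreachable).
fw_distances <- function(net) {
  n <- net$n
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges[r, 1]; j <- net$edges[r, 2]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Count shortest paths between every ordered pair by dynamic programming
# over the distance matrix: sigma[s,t] = sum over neighbours u of t with
# d(s,u) = d(s,t) - 1 of sigma[s,u].
path_counts <- function(net, d) {
  n <- net$n
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      for (u in net$adj[[t]])
        if (d[s, u] == d[s, t] - 1) sigma[s, t] <- sigma[s, t] + sigma[s, u]
    }
  }
  sigma
}

# Unnormalized betweenness over unordered pairs, by the combinatorial
# identity g_st(i) = sigma[s,i] * sigma[i,t] when d(s,i)+d(i,t) = d(s,t).
brute_betweenness <- function(net) {
  n <- net$n
  d <- fw_distances(net)
  sigma <- path_counts(net, d)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      if (is.finite(d[s, i]) && is.finite(d[i, t]) &&
          d[s, i] + d[i, t] == d[s, t])
        bc[i] <- bc[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
    }
  }
  stats::setNames(bc, net$labels)
}

# Component-scaled closeness from the Floyd-Warshall matrix.
brute_closeness <- function(net) {
  n <- net$n
  d <- fw_distances(net)
  cc <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) return(0)
    (length(di) / sum(di)) * (length(di) / (n - 1))
  }, numeric(1))
  stats::setNames(cc, net$labels)
}

# Literal pair-counting Kendall tau with ties excluded from the numerator.
brute_tau <- function(x, y) {
  n <- length(x)
  np <- 0; nm <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 || dy == 0) next
    if (sign(dx) == sign(dy)) np <- np + 1 else nm <- nm + 1
  }
  2 * (np - nm) / (n * (n - 1))
}

# Naive gravity score from the full distance matrix (no BFS truncation).
brute_gravity <- function(net, mass, radius) {
  d <- fw_distances(net)
  m <- as.numeric(mass[net$labels])
  s <- vapply(seq_len(net$n), function(i) {
    j <- which(d[i, ] >= 1 & d[i, ] <= radius)
    sum(m[i] * m[j] / d[i, j]^2)
  }, numeric(1))
  stats::setNames(s, net$labels)
}

# Direct transcriptions of the two published gravity instantiations,
# written independently of gravity_score().
direct_lgm <- function(net, radius) {
  k <- lengths(net$adj)
  brute_gravity(net, stats::setNames(as.numeric(k), net$labels), radius)
}
direct_gc <- function(net) {
  ks <- kshell_decompose(net)$shell
  brute_gravity(net, stats::setNames(as.numeric(ks), net$labels), 3)
}

# A connected random graph for property tests (retry until connected).
random_connected <- function(n, p, seed) {
  for (s in seed + 0:99) {
    g <- random_graph("er", n, p = p, rng_seed = s)
    if (g$m >= 1 &&
        length(bfs_distances(g, g$labels[1])) == g$n) return(g)
  }
  stop("no connected graph found")
}
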