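# Independent brute-force oracles used to validate the package's
# implementations. These are deliberately naive (double loops, full
# Floyd-Warshall, exhaustive path counting, union-find) and share no code
# with the package internals.

# Energy-distance statistic by literal double summation.
naive_energy_distance <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n1 <- nrow(x); n2 <- nrow(y)
  pd <- function(a, b) {
    s <- 0
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        s <- s + sqrt(sum((a[i, ] - b[j, ])^2))
      }
    }
    s
  }
  (n1 * n2 / (n1 + n2)) *
    (2 / (n1 * n2) * pd(x, y) - pd(x, x) / n1^2 - pd(y, y) / n2^2)
}

# All-pairs shortest paths by Floyd-Warshall.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# Per-node local clustering by direct triangle counting (degree < 2 -> 0).
brute_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

brute_global_efficiency <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

brute_char_path_length <- function(d) {
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) stop("fully disconnected")
  mean(fin)
}

brute_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    brute_global_efficiency(fw_distances(adj[nb, nb, drop = FALSE]))
  }, numeric(1)))
}

brute_nodal_efficiency <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(d) - 1)
}

# Shortest-path counts N[s, t], then betweenness by the fraction of s-t
# shortest paths through each node.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  N <- matrix(0, n, n)
  diag(N) <- 1
  for (s in seq_len(n)) {
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t]) || d[s, t] == 0) next
      nb <- which(adj[, t] != 0)
      pred <- nb[d[s, nb] == d[s, t] - 1]
      N[s, t] <- sum(N[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in seq.int(s + 1, n)) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          acc <- acc + N[s, v] * N[v, t] / N[s, t]
        }
      }
    }
    btw[v] <- acc
  }
  btw
}

# Connected components of an edge list by union-find.
uf_components <- function(region_a, region_b) {
  nodes <- sort(unique(c(region_a, region_b)))
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (k in seq_along(region_a)) {
    ra <- find(region_a[k]); rb <- find(region_b[k])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(region_a, find, numeric(1))
  split(seq_along(region_a), roots)
}

# Fixed small graphs -------------------------------------------------------

adj_complete <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0
  dimnames(a) <- list(1:n, 1:n)
  a
}

adj_cycle <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a[i, j] <- a[j, i] <- 1
  }
  dimnames(a) <- list(1:n, 1:n)
  a
}

adj_path <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  dimnames(a) <- list(1:n, 1:n)
  a
}

adj_star <- function(n_leaves) {
  n <- n_leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  dimnames(a) <- list(1:n, 1:n)
  a
}

# Random connected-ish binary graph on n nodes with m edges.
random_adjacency <- function(n, m) {
  pairs <- t(combn(n, 2))
  keep <- sample(nrow(pairs), m)
  a <- matrix(0, n, n, dimnames = list(1:n, 1:n))
  a[pairs[keep, , drop = FALSE]] <- 1
  a[pairs[keep, c(2, 1), drop = FALSE]] <- 1
  a
}

# Small simulated cohort shared across tests.
toy_cohort <- function(n_per_group = 10, n_regions = 10, seed = 42,
                       effect_regions = integer(0), effect_size = 0) {
  simulate_cohort(
    cohort_config(n_group_a = n_per_group, n_group_b = n_per_group,
                  vertices_per_region = c(20, 40),
                  effect_regions = effect_regions,
                  effect_size = effect_size, seed = seed),
    toy_scheme(n_regions)
  )
}
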