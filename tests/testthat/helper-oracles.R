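# Independent oracles used across the suite. Each re-derives the quantity
# under test by brute force (enumeration / exhaustive search), never via the
# implementation path it checks.

# Hypergeometric upper tail by exhaustive enumeration of draws: every
# n-subset of a universe of N genes of which the first K are annotated.
# Returns P(X >= k) for all k at once.
enum_hypergeom_tail <- function(K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # annotated genes are 1..K
  vapply(0:min(n, K), function(k) mean(hits >= k), numeric(1))
}

# Hand-executed BH step-up: for each input p, the minimum over ranks j at or
# above its own rank of p_(j) * m / j, capped at 1. Quadratic on purpose.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact betweenness by exhaustive simple-path enumeration: for every node
# pair, list all simple paths, keep the shortest, and credit each interior
# node with its fraction of those shortest paths. Each unordered pair
# counted once (undirected convention).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- seen
        return()
      }
      for (w in which(adj[v, ] == 1)) {
        if (!(w %in% seen)) walk(w, c(seen, w))
      }
    }
    walk(s, s)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  bc
}

# Adjacency matrix -> igraph
adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Small helper: random symmetric adjacency matrix on n nodes.
random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- as.integer(runif(length(upper)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}
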