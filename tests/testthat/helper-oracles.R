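# Independent brute-force oracles used to validate the graph metrics.
# Deliberately naive: Floyd-Warshall all-pairs paths and explicit loops,
# sharing no code with the package implementation.

fw_distances <- function(adj, w) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && adj[i, j] != 0) d[i, j] <- 1 - w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

brute_global_efficiency <- function(adj, w) {
  d <- fw_distances(adj, w)
  n <- nrow(adj)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  }
  s / (n * (n - 1))
}

brute_nodal_efficiency <- function(adj, w) {
  d <- fw_distances(adj, w)
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (n - 1)
  })
}

brute_local_efficiency <- function(adj, w) {
  n <- nrow(adj)
  e <- sapply(seq_len(n), function(i) {
    nbrs <- which(adj[i, ] != 0)
    m <- length(nbrs)
    if (m < 2) return(0)
    brute_global_efficiency(adj[nbrs, nbrs, drop = FALSE],
                            w[nbrs, nbrs, drop = FALSE])
  })
  list(e_local = mean(e), e_nodal_local = e)
}

brute_clustering <- function(adj) {
  n <- nrow(adj)
  c_i <- sapply(seq_len(n), function(i) {
    nbrs <- which(adj[i, ] != 0)
    k <- length(nbrs)
    if (k < 2) return(0)
    t_i <- 0
    for (a in seq_along(nbrs)) for (b in seq_along(nbrs)) {
      if (a < b && adj[nbrs[a], nbrs[b]] != 0) t_i <- t_i + 1
    }
    2 * t_i / (k * (k - 1))
  })
  list(c_p = mean(c_i), c_i = c_i)
}

brute_path_length <- function(adj, w) {
  d <- fw_distances(adj, w)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[ord[k]] <- min(1, min(p[ord[k:m]] * m / (k:m)))
  }
  adj
}

# Random connected-ish weighted graph on n nodes for oracle comparisons.
random_weighted_graph <- function(n, p_edge = 0.6) {
  repeat {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    on <- up[stats::runif(length(up)) < p_edge]
    if (length(on) >= 1) break
  }
  a[on] <- 1
  a <- a + t(a)
  w <- matrix(0, n, n)
  w[on] <- stats::runif(length(on), 0.05, 0.95)
  w <- w + t(w)
  list(adjacency = a, weights = w)
}

# Canonical planted-effect configuration used in power checks: five edges
# forming a path over odd-indexed nodes, correlation lowered by 0.3.
planted_path_edges <- function(delta = -0.3) {
  data.frame(roi_i = c(1, 3, 5, 7, 9), roi_j = c(3, 5, 7, 9, 11),
             delta_r = delta)
}

# Run fn over a vector of seeds, collecting scalar results.
with_seeds <- function(seeds, fn) {
  vapply(seeds, function(s) as.numeric(fn(s)), numeric(1))
}
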