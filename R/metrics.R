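#' Shortest-path length matrix of a thresholded network
#'
#' Edge distance is `1 - w` on retained edges (so stronger correlations
#' are "closer") and infinite elsewhere; path lengths are exact Dijkstra
#' shortest paths over those distances. Unreachable pairs are `Inf`.
#'
#' @param net A [thresholded_network()].
#' @return N x N symmetric matrix of shortest-path lengths, zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  dijkstra_lengths(net$adjacency, net$weights)
}

# Dijkstra over 1 - w distances via igraph; works on any (sub)graph.
dijkstra_lengths <- function(a, w) {
  n <- nrow(a)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  el <- which(a != 0 & upper.tri(a), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el))
    d <- igraph::distances(g, weights = 1 - w[el], algorithm = "dijkstra")
  } else {
    d <- igraph::distances(g)
  }
  unname(d)
}

#' Global efficiency
#'
#' The harmonic-mean-of-path-lengths measure of network integration:
#' `E_glob = (1 / (N(N-1))) * sum over i != j of 1 / L_path(i, j)`, with
#' `1 / Inf = 0` for disconnected pairs. Weights live on the correlation
#' scale, so with distances `1 - w < 1` the value can exceed 1; it is
#' reported unnormalized.
#'
#' @param net A [thresholded_network()].
#' @param paths Optional precomputed [shortest_path_lengths()] matrix.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(net, paths = NULL) {
  if (is.null(paths)) paths <- shortest_path_lengths(net)
  mean(nodal_efficiency(net, paths))
}

#' Nodal efficiency
#'
#' `E_i = (1 / (N-1)) * sum over j != i of 1 / L_path(i, j)`: how
#' efficiently node `i` exchanges information with the rest of the
#' network. The mean over nodes equals [global_efficiency()] exactly.
#'
#' @inheritParams global_efficiency
#' @return Numeric vector of length N (named by node labels).
#' @export
nodal_efficiency <- function(net, paths = NULL) {
  if (is.null(paths)) paths <- shortest_path_lengths(net)
  n <- nrow(paths)
  inv <- 1 / paths  # 1/Inf = 0 handles disconnected pairs
  diag(inv) <- 0
  e <- rowSums(inv) / (n - 1)
  names(e) <- net$labels
  e
}

#' Local efficiency, global and per node
#'
#' For each node `i`, the subgraph induced by its direct neighbors (node
#' `i` excluded, retained weights kept) is formed and the global-
#' efficiency formula evaluated on it; nodes with fewer than two neighbors
#' score 0. `E_loc` is the mean of the per-node values.
#'
#' @param net A [thresholded_network()].
#' @return List with `e_local` (scalar mean) and `e_nodal_local` (vector).
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  n <- net$n_nodes
  e_nodal <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(net$adjacency[i, ] != 0)
    if (length(nbrs) < 2) next
    a_sub <- net$adjacency[nbrs, nbrs, drop = FALSE]
    w_sub <- net$weights[nbrs, nbrs, drop = FALSE]
    d <- dijkstra_lengths(a_sub, w_sub)
    inv <- 1 / d
    diag(inv) <- 0
    m <- length(nbrs)
    e_nodal[i] <- sum(inv) / (m * (m - 1))
  }
  names(e_nodal) <- net$labels
  list(e_local = mean(e_nodal), e_nodal_local = e_nodal)
}

#' Clustering coefficients
#'
#' Binary clustering: `C_i = 2 T_i / (K_i (K_i - 1))` where `T_i` counts
#' edges among node `i`'s neighbors and `K_i` is its degree; `C_i = 0`
#' when `K_i < 2`. `C_p` is the mean over nodes.
#'
#' @param net A [thresholded_network()].
#' @return List with `c_p` (scalar) and `c_i` (per-node vector).
#' @export
clustering_coefficients <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  a <- net$adjacency
  k <- rowSums(a)
  t_i <- diag(a %*% a %*% a) / 2
  c_i <- ifelse(k < 2, 0, 2 * t_i / (k * (k - 1)))
  names(c_i) <- net$labels
  list(c_p = mean(c_i), c_i = c_i)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs. Disconnected
#' pairs are excluded from the average and counted separately; a network
#' with no edges has no defined path length and raises an error.
#'
#' @inheritParams global_efficiency
#' @return List with `l_p` (scalar) and `n_disconnected_pairs` (count of
#'   unordered unreachable pairs).
#' @export
characteristic_path_length <- function(net, paths = NULL) {
  if (is.null(paths)) paths <- shortest_path_lengths(net)
  off <- paths[upper.tri(paths)]
  finite <- is.finite(off)
  if (!any(finite)) {
    stop("characteristic path length undefined: network has no connected pairs",
         call. = FALSE)
  }
  list(l_p = mean(off[finite]), n_disconnected_pairs = sum(!finite))
}

#' All topology metrics of a thresholded network
#'
#' One-stop computation sharing a single shortest-path evaluation.
#'
#' @param net A [thresholded_network()].
#' @return List with `global` (one-row tibble: `sparsity`, `n_edges`,
#'   `e_glob`, `e_loc`, `c_p`, `l_p`, `n_disconnected_pairs`) and `nodal`
#'   (tibble: `node`, `label`, `degree`, `e_nodal`, `e_nodal_local`,
#'   `c_i`).
#' @export
network_metrics <- function(net) {
  paths <- shortest_path_lengths(net)
  e_i <- nodal_efficiency(net, paths)
  loc <- local_efficiency(net)
  cl <- clustering_coefficients(net)
  cp <- characteristic_path_length(net, paths)
  list(
    global = tibble::tibble(
      sparsity = net$sparsity, n_edges = net$n_edges,
      e_glob = mean(e_i), e_loc = loc$e_local, c_p = cl$c_p, l_p = cp$l_p,
      n_disconnected_pairs = cp$n_disconnected_pairs
    ),
    nodal = tibble::tibble(
      node = seq_len(net$n_nodes), label = net$labels, degree = net$degree,
      e_nodal = unname(e_i), e_nodal_local = unname(loc$e_nodal_local),
      c_i = unname(cl$c_i)
    )
  )
}
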