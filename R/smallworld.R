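#' Degree-preserving random-network ensemble
#'
#' Matched null networks for small-world normalization: each member is
#' produced by degree-preserving double-edge swaps (about
#' `swaps_per_edge` successful swaps per edge), after which the original
#' edge-weight multiset is randomly reassigned to the rewired edges. Every
#' member therefore has exactly the source network's degree sequence, edge
#' count, and weight multiset, but randomized topology.
#'
#' Networks too small or too dense to rewire (fewer than two edges, or a
#' complete graph) fall back to weight permutation on the fixed topology,
#' with a warning.
#'
#' @param net A [thresholded_network()].
#' @param n_rand Number of null networks (default 100).
#' @param seed Optional integer seed (global RNG state is restored).
#' @param swaps_per_edge Rewiring effort per edge (default 10).
#' @return Object of class `random_ensemble`: list with `members` (list of
#'   `thresholded_network`), `n_rand`, `seed`.
#' @export
random_ensemble <- function(net, n_rand = 100, seed = NULL,
                            swaps_per_edge = 10) {
  stopifnot(inherits(net, "thresholded_network"), n_rand >= 1)
  m <- net$n_edges
  n <- net$n_nodes
  complete <- m == n * (n - 1) / 2
  if (m < 2 || complete) {
    warning("network cannot be rewired (too small or complete); ",
            "falling back to weight permutation only", call. = FALSE)
  }
  wvals <- net$weights[net$adjacency != 0 & upper.tri(net$adjacency)]
  g0 <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  build <- function() {
    if (m < 2 || complete) {
      a <- net$adjacency
    } else {
      g <- igraph::rewire(g0, igraph::keeping_degseq(niter = swaps_per_edge * m))
      a <- unname(as.matrix(igraph::as_adjacency_matrix(g)))
    }
    el <- which(a != 0 & upper.tri(a), arr.ind = TRUE)
    w <- matrix(0, n, n)
    w[el] <- sample(wvals, length(wvals))
    w <- w + t(w)
    thresholded_network(a, w, labels = net$labels, sparsity = net$sparsity)
  }
  members <- if (is.null(seed)) {
    replicate(n_rand, build(), simplify = FALSE)
  } else {
    with_preserved_rng(seed, replicate(n_rand, build(), simplify = FALSE))
  }
  structure(list(members = members, n_rand = n_rand, seed = seed),
            class = "random_ensemble")
}

#' Small-world indices against a matched random ensemble
#'
#' Computes `gamma = C_p / C_p_rand`, `lambda = L_p / L_p_rand`, and
#' `sigma = gamma / lambda`, where `C_p_rand` and `L_p_rand` are ensemble
#' means over degree-preserving random networks. The network is classified
#' small-world when `gamma > 1` and `lambda` is close to 1 (within
#' `lambda_tol`) or, equivalently under the ratio criterion, `sigma > 1`.
#'
#' @param net A [thresholded_network()].
#' @param ensemble Optional [random_ensemble()]; built with `n_rand` and
#'   `seed` when missing.
#' @param n_rand,seed Passed to [random_ensemble()] when `ensemble` is
#'   `NULL`.
#' @param lambda_tol Half-width of the "lambda approximately 1" band
#'   (default 0.15).
#' @return One-row tibble: `c_p`, `l_p`, `c_p_rand`, `l_p_rand`, `gamma`,
#'   `lambda`, `sigma`, `small_world`, `reason` (why classification failed,
#'   `NA` otherwise).
#' @export
small_worldness <- function(net, ensemble = NULL, n_rand = 100, seed = NULL,
                            lambda_tol = 0.15) {
  stopifnot(inherits(net, "thresholded_network"))
  if (is.null(ensemble)) ensemble <- random_ensemble(net, n_rand, seed)
  cl <- clustering_coefficients(net)
  lp <- characteristic_path_length(net)
  stats <- vapply(ensemble$members, function(mem) {
    c(clustering_coefficients(mem)$c_p, characteristic_path_length(mem)$l_p)
  }, numeric(2))
  c_p_rand <- mean(stats[1, ])
  l_p_rand <- mean(stats[2, ])
  if (c_p_rand == 0) {
    return(tibble::tibble(
      c_p = cl$c_p, l_p = lp$l_p, c_p_rand = c_p_rand, l_p_rand = l_p_rand,
      gamma = NA_real_, lambda = lp$l_p / l_p_rand, sigma = NA_real_,
      small_world = FALSE,
      reason = "ensemble mean clustering is zero; gamma undefined"
    ))
  }
  gamma <- cl$c_p / c_p_rand
  lambda <- lp$l_p / l_p_rand
  sigma <- gamma / lambda
  tibble::tibble(
    c_p = cl$c_p, l_p = lp$l_p, c_p_rand = c_p_rand, l_p_rand = l_p_rand,
    gamma = gamma, lambda = lambda, sigma = sigma,
    small_world = gamma > 1 && (abs(lambda - 1) <= lambda_tol || sigma > 1),
    reason = NA_character_
  )
}

#' Ring-lattice graph with random rewiring (Watts-Strogatz style)
#'
#' Convenience generator for small-world validation: an N-node ring where
#' each node connects to its `k` nearest neighbors, with each edge endpoint
#' rewired with probability `p`.
#'
#' @param n_nodes Number of nodes.
#' @param k Even neighborhood size (edges per node in the lattice).
#' @param p Rewiring probability.
#' @return A [thresholded_network()] with unit edge distances.
#' @export
ring_lattice_network <- function(n_nodes = 12, k = 4, p = 0.1) {
  g <- igraph::sample_smallworld(1, n_nodes, k / 2, p)
  g <- igraph::simplify(g)
  thresholded_network(unname(as.matrix(igraph::as_adjacency_matrix(g))))
}

#' Erdos-Renyi random graph with a fixed edge count
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges (density-matched nulls).
#' @return A [thresholded_network()] with unit edge distances.
#' @export
random_network <- function(n_nodes = 12, n_edges = 24) {
  g <- igraph::sample_gnm(n_nodes, n_edges)
  thresholded_network(unname(as.matrix(igraph::as_adjacency_matrix(g))))
}
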