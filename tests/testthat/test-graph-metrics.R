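complete_binary <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0
  thresholded_network(a)
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  thresholded_network(a)
}

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  thresholded_network(a)
}

test_that("sparsity thresholding keeps the strongest edges at the right count", {
  set.seed(6)
  # a shared component keeps all pairwise correlations positive
  shared <- rnorm(20)
  fc <- compute_fc(sapply(1:12, function(i) shared + rnorm(20)))
  net <- threshold_by_sparsity(fc, 0.5)
  expect_equal(net$n_edges, 33)          # round(0.5 * 66)
  expect_equal(net$sparsity, 0.5)
  expect_equal(unname(rowSums(net$adjacency)), net$degree)
  # retained weights live exactly on the adjacency support
  expect_true(all((net$weights != 0) <= (net$adjacency == 1)))
  # kept edges are the strongest nonnegative ones
  w <- pmax(unclass(fc), 0)
  kept_w <- w[net$adjacency == 1 & upper.tri(w)]
  dropped_w <- w[net$adjacency == 0 & upper.tri(w)]
  expect_gte(min(kept_w), max(dropped_w))

  # s = 1 on an all-positive matrix gives the complete graph
  pos <- matrix(0.5, 12, 12); diag(pos) <- 0
  pos <- pos + matrix(runif(144, 0, 0.1), 12, 12)
  pos <- (pos + t(pos)) / 2; diag(pos) <- 0
  full <- threshold_by_sparsity(pos, 1)
  expect_equal(full$degree, rep(11L, 12))
})

test_that("thresholding warns and keeps all edges when positives run out", {
  w <- matrix(-0.5, 8, 8)
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 8))
  for (k in seq_len(nrow(pairs))) {
    w[pairs[k, 1], pairs[k, 2]] <- w[pairs[k, 2], pairs[k, 1]] <- 0.4
  }
  diag(w) <- 0
  expect_warning(net <- threshold_by_sparsity(w, 10 / 28), "positive weight")
  expect_equal(net$n_edges, 7)
})

test_that("tie-breaking in thresholding is deterministic", {
  w <- matrix(0.5, 6, 6); diag(w) <- 0  # all weights tied
  a <- threshold_by_sparsity(w, 0.3)
  b <- threshold_by_sparsity(w, 0.3)
  expect_identical(a$adjacency, b$adjacency)
  expect_equal(a$n_edges, 5)  # round(0.3 * 15) = 5, first pairs in (i, j) order
  expect_equal(which(a$adjacency[1, ] == 1), 2:6)
})

test_that("shortest paths match hand calculations and the 1 - w transform", {
  # 3-node chain, w = 1 on both edges: zero-length paths (capped near 0)
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  w1 <- a * 1
  net1 <- thresholded_network(a, w1)
  d1 <- shortest_path_lengths(net1)
  expect_lt(d1[1, 3], 1e-5)
  # w = 0.5 on both edges: 1 - w = 0.5 per hop, two hops = 1.0
  net05 <- thresholded_network(a, a * 0.5)
  d05 <- shortest_path_lengths(net05)
  expect_equal(d05[1, 3], 1.0)
  expect_equal(d05[1, 2], 0.5)
  # complete graph with w -> 1: all off-diagonal path lengths ~ 0
  dc <- shortest_path_lengths(thresholded_network(1 - diag(4), (1 - diag(4))))
  expect_lt(max(dc), 1e-5)
  # disconnected nodes are infinitely far
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  d_iso <- shortest_path_lengths(thresholded_network(iso))
  expect_equal(d_iso[1, 3], Inf)
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(7)
  for (rep in 1:120) {
    n <- sample(3:6, 1)
    g <- random_weighted_graph(n)
    net <- thresholded_network(g$adjacency, g$weights)
    paths <- shortest_path_lengths(net)
    fw <- fw_distances(g$adjacency, g$weights)
    expect_true(all((is.infinite(paths) & is.infinite(fw)) |
                      abs(paths - fw) < 1e-10))
    expect_equal(global_efficiency(net, paths),
                 brute_global_efficiency(g$adjacency, g$weights),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_efficiency(net, paths)),
                 brute_nodal_efficiency(g$adjacency, g$weights),
                 tolerance = 1e-10)
    loc <- local_efficiency(net)
    bl <- brute_local_efficiency(g$adjacency, g$weights)
    expect_equal(unname(loc$e_nodal_local), bl$e_nodal_local,
                 tolerance = 1e-10)
    cl <- clustering_coefficients(net)
    bc <- brute_clustering(g$adjacency)
    expect_equal(unname(cl$c_i), bc$c_i, tolerance = 1e-12)
    if (any(is.finite(paths[upper.tri(paths)]))) {
      expect_equal(characteristic_path_length(net, paths)$l_p,
                   brute_path_length(g$adjacency, g$weights),
                   tolerance = 1e-10)
    }
  }
})

test_that("canonical graphs give their closed-form metric values", {
  comp <- complete_binary(6)
  m <- network_metrics(comp)
  expect_equal(m$global$e_glob, 1)
  expect_equal(m$global$c_p, 1)
  expect_equal(m$global$l_p, 1)

  # complete graph with uniform w = 0.5: all path lengths 0.5, E_glob = 2
  compw <- thresholded_network(1 - diag(6), (1 - diag(6)) * 0.5)
  expect_equal(global_efficiency(compw), 2)

  # star: center perfectly efficient, leaves 2/3 (binary distances, N = 4)
  st <- star_graph(4)
  e <- nodal_efficiency(st)
  expect_equal(unname(e[1]), 1)
  expect_equal(unname(e[2]), (1 + 0.5 + 0.5) / 3)
  expect_equal(clustering_coefficients(st)$c_p, 0)
  expect_equal(unname(local_efficiency(st)$e_nodal_local), rep(0, 4))

  # 4-node path graph: L_p = (1*3 + 2*2 + 3*1) / 6 = 5/3
  expect_equal(characteristic_path_length(path_graph(4))$l_p, 5 / 3)

  # one edge removed from complete binary graph at N = 4: E = 11/12
  a <- 1 - diag(4); a[1, 2] <- a[2, 1] <- 0
  expect_equal(global_efficiency(thresholded_network(a)), 11 / 12)

  # triangle: full clustering and local efficiency
  tri <- complete_binary(3)
  expect_equal(unname(clustering_coefficients(tri)$c_i), rep(1, 3))
  expect_equal(local_efficiency(tri)$e_local, 1)

  # node with 3 neighbors, 2 edges among them: C_i = 2*2/(3*2) = 2/3
  a5 <- matrix(0, 4, 4)
  a5[1, 2:4] <- a5[2:4, 1] <- 1
  a5[2, 3] <- a5[3, 2] <- 1; a5[3, 4] <- a5[4, 3] <- 1
  expect_equal(unname(clustering_coefficients(thresholded_network(a5))$c_i[1]),
               2 / 3)

  # two disconnected cliques: cross pairs contribute zero efficiency
  blocks <- matrix(0, 6, 6)
  blocks[1:3, 1:3] <- 1 - diag(3); blocks[4:6, 4:6] <- 1 - diag(3)
  bn <- thresholded_network(blocks)
  expect_equal(global_efficiency(bn), (6 * 2) / (6 * 5))
  expect_equal(characteristic_path_length(bn)$n_disconnected_pairs, 9)

  # an edgeless graph has no defined path length
  expect_error(characteristic_path_length(thresholded_network(diag(0, 4))),
               "no connected pairs")
})

test_that("algebraic identities hold and metrics are permutation invariant", {
  set.seed(8)
  fc <- compute_fc(matrix(rnorm(50 * 12), 50, 12))
  net <- threshold_by_sparsity(fc, 0.3)
  m <- network_metrics(net)
  expect_equal(mean(m$nodal$e_nodal), m$global$e_glob, tolerance = 1e-12)
  expect_equal(mean(m$nodal$e_nodal_local), m$global$e_loc, tolerance = 1e-12)
  expect_equal(mean(m$nodal$c_i), m$global$c_p, tolerance = 1e-12)

  perm <- sample(12)
  w <- unclass(fc)[perm, perm]
  mp <- network_metrics(threshold_by_sparsity(w, 0.3))
  expect_equal(mp$global$e_glob, m$global$e_glob, tolerance = 1e-10)
  expect_equal(mp$global$c_p, m$global$c_p, tolerance = 1e-10)
  expect_equal(mp$global$l_p, m$global$l_p, tolerance = 1e-10)
  expect_equal(mp$nodal$e_nodal[order(perm)], m$nodal$e_nodal,
               tolerance = 1e-10)
})

test_that("global efficiency never decreases as sparsity grows", {
  set.seed(9)
  for (rep in 1:5) {
    fc <- compute_fc(matrix(rnorm(40 * 12), 40, 12))
    effs <- sapply(seq(0.1, 0.5, by = 0.05), function(s) {
      global_efficiency(threshold_by_sparsity(fc, s))
    })
    expect_true(all(diff(effs) >= -1e-12))
  }
})

test_that("random ensembles preserve degree sequence and weight multiset", {
  set.seed(10)
  fc <- compute_fc(matrix(rnorm(40 * 12), 40, 12))
  net <- threshold_by_sparsity(fc, 0.25)
  ens <- random_ensemble(net, n_rand = 12, seed = 3)
  src_w <- sort(net$weights[upper.tri(net$weights) & net$adjacency == 1])
  for (mem in ens$members) {
    expect_equal(sort(mem$degree), sort(net$degree))
    expect_equal(mem$n_edges, net$n_edges)
    expect_equal(sort(mem$weights[upper.tri(mem$weights) & mem$adjacency == 1]),
                 src_w, tolerance = 1e-12)
  }
  # seeded ensembles reproduce
  ens2 <- random_ensemble(net, n_rand = 12, seed = 3)
  expect_identical(lapply(ens$members, `[[`, "adjacency"),
                   lapply(ens2$members, `[[`, "adjacency"))
  # complete graphs cannot be rewired
  expect_warning(random_ensemble(complete_binary(5), n_rand = 2),
                 "cannot be rewired")
})

test_that("rewiring destroys lattice clustering", {
  lattice <- ring_lattice_network(12, 4, 0)  # pure ring lattice, C_p = 0.5
  cp_lattice <- clustering_coefficients(lattice)$c_p
  ens <- random_ensemble(lattice, n_rand = 20, seed = 4)
  cp_rand <- mean(sapply(ens$members,
                         function(m) clustering_coefficients(m)$c_p))
  expect_gt(cp_lattice, 1.5 * cp_rand)
})

test_that("small-worldness is ratio-1 against a degenerate ensemble", {
  net <- ring_lattice_network(12, 4, 0.1)
  ens <- structure(list(members = replicate(5, net, simplify = FALSE),
                        n_rand = 5, seed = NULL),
                   class = "random_ensemble")
  sw <- small_worldness(net, ensemble = ens)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("gamma is undefined when the null ensemble has no clustering", {
  # a star cannot be rewired (all edges share the hub), so every ensemble
  # member is again a star with C_p = 0
  st <- star_graph(5)
  sw <- small_worldness(st, n_rand = 3)
  expect_false(sw$small_world)
  expect_match(sw$reason, "gamma undefined")
})

test_that("topology profiles cover the sparsity grid with exact identities", {
  set.seed(11)
  fc <- compute_fc(matrix(rnorm(60 * 12), 60, 12))
  prof <- profile_topology(fc, n_rand = 10, seed = 5, subject_id = "s1")
  expect_equal(sort(unique(prof$global$sparsity)), seq(0.10, 0.50, by = 0.05))
  expect_length(unique(prof$global$sparsity), 9)

  wide_g <- tidyr::pivot_wider(prof$global, names_from = "metric",
                               values_from = "value")
  wide_n <- tidyr::pivot_wider(prof$nodal, names_from = "metric",
                               values_from = "value")
  for (s in unique(wide_g$sparsity)) {
    g <- wide_g[wide_g$sparsity == s, ]
    n <- wide_n[wide_n$sparsity == s, ]
    expect_equal(mean(n$e_nodal), g$e_glob, tolerance = 1e-10)
    expect_equal(mean(n$e_nodal_local), g$e_loc, tolerance = 1e-10)
    expect_equal(mean(n$c_i), g$c_p, tolerance = 1e-10)
  }

  # deterministic given (fc, seed)
  prof2 <- profile_topology(fc, n_rand = 10, seed = 5, subject_id = "s1")
  expect_identical(prof$global, prof2$global)
  expect_identical(prof$auc, prof2$auc)
})

test_that("the AUC of a constant metric equals 0.4 times its value", {
  # constant-by-construction: e_glob of a complete binary support is 1 at
  # every sparsity only when the matrix is complete; instead verify the
  # trapezoid identity directly on a profile metric forced constant
  sp <- seq(0.10, 0.50, by = 0.05)
  expect_equal(dmnet:::trapezoid_auc(sp, rep(3.7, 9)), 0.4 * 3.7,
               tolerance = 1e-12)
  expect_equal(dmnet:::trapezoid_auc(sp, sp), 0.5 * (0.5^2 - 0.1^2),
               tolerance = 1e-12)
})
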