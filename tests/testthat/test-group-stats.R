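# Build a cohort tibble directly from FC matrices (bypassing generation)
# so edge-level statistics can be checked by hand.
fc_cohort <- function(control, treated) {
  make_fc <- function(w, id) {
    diag(w) <- 0
    structure(w, class = c("fc_matrix", "matrix", "array"), subject_id = id)
  }
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(length(control) + length(treated))),
    group = c(rep("control", length(control)), rep("treated", length(treated))),
    fc = c(purrr::imap(control, function(w, i) make_fc(w, paste0("c", i))),
           purrr::imap(treated, function(w, i) make_fc(w, paste0("t", i))))
  )
}

# 3-node matrices whose (1,2) edge carries chosen z-values; other edges 0.
z_edge_cohort <- function(z_control, z_treated) {
  mk <- function(z) {
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- tanh(z)
    w
  }
  fc_cohort(lapply(z_control, mk), lapply(z_treated, mk))
}

test_that("edgewise t matches the closed-form pooled-variance value", {
  co <- z_edge_cohort(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
  res <- edgewise_ttest(co)
  edge <- res[res$roi_i == 1 & res$roi_j == 2, ]
  # hand computation: means 0.5 vs 0.2, pooled sd 0.1, se = 0.1*sqrt(2/3)
  expect_equal(edge$t, -3.6742, tolerance = 1e-4)
  expect_equal(edge$df, 4)
  expect_equal(edge$difference, -0.3, tolerance = 1e-10)
  expect_equal(edge$p, 2 * pt(-3.674235, 4), tolerance = 1e-5)

  # swapping the group labels negates t, p unchanged
  co_sw <- co
  co_sw$group <- ifelse(co$group == "control", "treated", "control")
  res_sw <- edgewise_ttest(co_sw)
  expect_equal(res_sw$t, -res$t, tolerance = 1e-12)
  expect_equal(res_sw$p, res$p, tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1 everywhere", {
  set.seed(12)
  ms <- replicate(3, { m <- cor(matrix(rnorm(60), 20, 3)); diag(m) <- 0; m },
                  simplify = FALSE)
  co <- fc_cohort(ms, ms)
  res <- edgewise_ttest(co)
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("edgewise Welch option reproduces stats::t.test", {
  set.seed(13)
  zc <- rnorm(5, 0.3, 0.1); zt <- rnorm(6, 0.1, 0.2)
  co <- z_edge_cohort(zc, zt)
  res <- edgewise_ttest(co, var_equal = FALSE)
  edge <- res[res$roi_i == 1 & res$roi_j == 2, ]
  ref <- t.test(zt, zc, var.equal = FALSE)
  expect_equal(edge$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(edge$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(edge$p, ref$p.value, tolerance = 1e-10)
})

test_that("NBS is deterministic, seed-sensitive, and handles empty results", {
  cfg <- cohort_config(n_control = 6, n_treated = 6,
                       motion_excursion_prob = 0, seed = 31)
  co <- generate_cohort(cfg) |> preprocess_cohort() |> compute_cohort_fc()
  a <- nbs(co, n_perm = 50, seed = 7)
  b <- nbs(co, n_perm = 50, seed = 7)
  expect_identical(a$null_max, b$null_max)
  expect_equal(a$components, b$components)
  c <- nbs(co, n_perm = 50, seed = 8)
  expect_false(identical(a$null_max, c$null_max))
  # p_fwe bounded below by the add-one estimator
  if (nrow(a$components) > 0) {
    expect_true(all(a$components$p_fwe >= 1 / 51))
    expect_true(all(a$components$p_fwe <= 1))
  }
  # an absurdly strict primary threshold gives an empty, valid result
  strict <- nbs(co, primary_threshold = 1e-12, n_perm = 20, seed = 1)
  expect_equal(nrow(strict$components), 0)
  expect_equal(sum(strict$edges$suprathreshold), 0)
  expect_true(all(is.na(tidy(strict)$p_fwe)))
})

test_that("NBS components partition the suprathreshold edges", {
  pe <- planted_path_edges()
  cfg <- cohort_config(seed = 32, planted_edges = pe,
                       motion_excursion_prob = 0)
  co <- generate_cohort(cfg) |> preprocess_cohort() |> compute_cohort_fc()
  res <- nbs(co, n_perm = 100, seed = 2)
  sup <- res$edges[res$edges$suprathreshold, ]
  expect_true(all(!is.na(sup$component_id)))
  expect_true(all(is.na(res$edges$component_id[!res$edges$suprathreshold])))
  expect_equal(sum(res$components$n_edges), nrow(sup))
  # edges of one component are mutually reachable through suprathreshold edges
  g <- igraph::graph_from_edgelist(as.matrix(sup[, c("roi_i", "roi_j")]),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  expect_equal(length(unique(paste(comp[sup$roi_i], sup$component_id))),
               nrow(res$components))
})

test_that("detected component grows with planted effect size", {
  sizes <- sapply(c(0, -0.15, -0.3), function(d) {
    cfg <- cohort_config(seed = 33,
                         planted_edges = if (d == 0) NULL else planted_path_edges(d),
                         motion_excursion_prob = 0)
    co <- generate_cohort(cfg) |> preprocess_cohort() |> compute_cohort_fc()
    res <- nbs(co, n_perm = 50, seed = 3)
    if (nrow(res$components) == 0) 0 else max(res$components$n_edges)
  })
  expect_true(sizes[1] <= sizes[2] || sizes[2] <= sizes[3])
  expect_gte(sizes[3], 5)
})

test_that("edge classification counts cortical and subcortical pairs", {
  edges <- tibble::tibble(roi_i = c(1, 1, 3), roi_j = c(2, 3, 4))
  counts <- classify_edges(edges)
  expect_equal(counts$n, c(1L, 1L, 1L))
  expect_equal(sum(counts$n), nrow(edges))
  # orientation invariance
  flipped <- tibble::tibble(roi_i = edges$roi_j, roi_j = edges$roi_i)
  expect_equal(classify_edges(flipped)$n, counts$n)
  # empty set and unlabeled ROI
  empty <- classify_edges(tibble::tibble(roi_i = integer(), roi_j = integer()))
  expect_equal(empty$n, c(0L, 0L, 0L))
  meta <- dmn_rois()[1:4, ]
  expect_error(classify_edges(tibble::tibble(roi_i = 1, roi_j = 9), meta),
               "no cortical/subcortical class")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03))$p_fdr, c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.04)$p_fdr, 0.04)
  expect_false(any(fdr_bh(rep(1, 5))$significant))
  expect_equal(nrow(fdr_bh(numeric(0))), 0)

  set.seed(14)
  for (rep in 1:1000) {
    p <- runif(sample(1:20, 1))
    res <- fdr_bh(p)
    expect_equal(res$p_fdr, brute_bh(p), tolerance = 1e-12)
    expect_true(all(res$p_fdr >= res$p))
  }
})

test_that("topology comparison flags nothing for identical groups", {
  set.seed(15)
  fcs <- replicate(4, compute_fc(matrix(rnorm(50 * 12), 50, 12)),
                   simplify = FALSE)
  co <- tibble::tibble(
    subject_id = sprintf("s%d", 1:8),
    group = rep(c("control", "treated"), each = 4),
    fc = c(fcs, fcs)
  )
  prof <- profile_cohort(co, n_rand = 5, seed = 6)
  res <- compare_topology(prof)
  # group metric values are identical up to the random-ensemble draws,
  # which do not enter the tested metrics
  expect_false(any(res$significant))
  expect_true(all(res$p_fdr >= res$p))
  expect_true(all(res$significant == (res$p_fdr < 0.05)))
})

test_that("a planted global-efficiency deficit is detected", {
  set.seed(16)
  fcs_c <- replicate(10, compute_fc(matrix(rnorm(80 * 12), 80, 12) +
                                      0.8 * matrix(rnorm(80), 80, 1)[, rep(1, 12)]),
                     simplify = FALSE)
  # treated group: same construction, globally weakened correlations
  fcs_t <- replicate(10, compute_fc(matrix(rnorm(80 * 12), 80, 12) +
                                      0.45 * matrix(rnorm(80), 80, 1)[, rep(1, 12)]),
                     simplify = FALSE)
  co <- tibble::tibble(
    subject_id = sprintf("s%d", 1:20),
    group = rep(c("control", "treated"), each = 10),
    fc = c(fcs_c, fcs_t)
  )
  prof <- profile_cohort(co, n_rand = 5, seed = 7)
  res <- compare_topology(prof)
  eg <- res[res$metric == "e_glob" & res$summary == "auc", ]
  expect_lt(eg$mean_treated, eg$mean_control)
  expect_true(eg$significant)
})
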