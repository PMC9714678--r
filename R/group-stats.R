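# Stack FC matrices into a subjects x edges matrix (upper-triangle order),
# optionally Fisher z-transformed. Attributes carry the edge index map.
edge_value_stack <- function(fc_list, use_fisher_z = TRUE) {
  fc_list <- fc_list[!vapply(fc_list, is.null, logical(1))]
  stopifnot(length(fc_list) >= 1)
  n <- nrow(fc_list[[1]])
  labels <- rownames(fc_list[[1]])
  if (is.null(labels)) labels <- as.character(seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vals <- t(vapply(fc_list, function(fc) {
    stopifnot(nrow(fc) == n)
    m <- if (use_fisher_z) fisher_z(fc) else unclass(fc)
    m[idx]
  }, numeric(nrow(idx))))
  structure(vals, edge_index = idx, labels = labels, n_nodes = n)
}

# Vectorized two-sample t over columns for many label permutations at once.
# values: n_subj x n_edges; assign: n_perm x n_subj 0/1 membership of group A.
perm_tstats <- function(values, assign, n_a, n_b, var_equal = TRUE) {
  sums <- assign %*% values
  sqs <- assign %*% values^2
  tot <- matrix(colSums(values), nrow(assign), ncol(values), byrow = TRUE)
  tot2 <- matrix(colSums(values^2), nrow(assign), ncol(values), byrow = TRUE)
  mean_a <- sums / n_a
  mean_b <- (tot - sums) / n_b
  ss_a <- sqs - n_a * mean_a^2
  ss_b <- (tot2 - sqs) - n_b * mean_b^2
  if (var_equal) {
    df <- n_a + n_b - 2
    sp2 <- (ss_a + ss_b) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    t <- (mean_a - mean_b) / se
    t[se == 0] <- 0
    list(t = t, df = matrix(df, nrow(t), ncol(t)), mean_a = mean_a,
         mean_b = mean_b)
  } else {
    va <- ss_a / (n_a - 1)
    vb <- ss_b / (n_b - 1)
    se2 <- va / n_a + vb / n_b
    t <- (mean_a - mean_b) / sqrt(se2)
    t[se2 == 0] <- 0
    df <- se2^2 / ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
    df[se2 == 0] <- n_a + n_b - 2
    list(t = t, df = df, mean_a = mean_a, mean_b = mean_b)
  }
}

#' Edgewise two-sample t-tests between groups
#'
#' Two-sided two-sample t-test per off-diagonal edge, comparing treated
#' against control subjects (difference and t are treated minus control).
#' Tests operate on Fisher z-transformed correlations by default; the
#' pooled-variance test is the default, with Welch available. Edges with
#' zero variance in both groups get `t = 0`, `p = 1`.
#'
#' @param cohort A cohort tibble with `fc` list-column and `group` column
#'   (`"control"`/`"treated"`, or any two levels — the first sorted level
#'   is the reference).
#' @param use_fisher_z Test on `atanh(r)` (default) or raw correlations.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return A tibble with one row per edge: `roi_i`, `roi_j`, `label_i`,
#'   `label_j`, `mean_control`, `mean_treated`, `difference`, `t`, `df`,
#'   `p`.
#' @export
edgewise_ttest <- function(cohort, use_fisher_z = TRUE, var_equal = TRUE) {
  groups <- split_fc_groups(cohort)
  stack <- edge_value_stack(c(groups$treated, groups$control), use_fisher_z)
  n_a <- length(groups$treated)
  n_b <- length(groups$control)
  stopifnot(n_a >= 2, n_b >= 2)
  assign <- matrix(c(rep(1, n_a), rep(0, n_b)), 1)
  ts <- perm_tstats(stack, assign, n_a, n_b, var_equal)
  idx <- attr(stack, "edge_index")
  labels <- attr(stack, "labels")
  tibble::tibble(
    roi_i = idx[, 1], roi_j = idx[, 2],
    label_i = labels[idx[, 1]], label_j = labels[idx[, 2]],
    mean_control = as.numeric(ts$mean_b), mean_treated = as.numeric(ts$mean_a),
    difference = as.numeric(ts$mean_a - ts$mean_b),
    t = as.numeric(ts$t), df = as.numeric(ts$df),
    p = 2 * stats::pt(-abs(as.numeric(ts$t)), as.numeric(ts$df))
  )
}

split_fc_groups <- function(cohort) {
  stopifnot(is.data.frame(cohort), all(c("fc", "group") %in% names(cohort)))
  keep <- !vapply(cohort$fc, is.null, logical(1))
  cohort <- cohort[keep, ]
  lev <- sort(unique(cohort$group))
  if (length(lev) != 2) stop("exactly two groups required; got ",
                             paste(lev, collapse = ", "), call. = FALSE)
  reference <- if ("control" %in% lev) "control" else lev[1]
  other <- setdiff(lev, reference)
  list(control = cohort$fc[cohort$group == reference],
       treated = cohort$fc[cohort$group == other],
       levels = c(reference, other))
}

# Connected components over an edge list; returns per-edge component ids
# (edges sharing a node are in the same component). Simple union-find.
edge_components <- function(i, j, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(i, find, integer(1))
  match(roots, unique(roots))
}

#' Network-based statistic (NBS) group comparison
#'
#' Family-wise-error-corrected inference on connected components of
#' suprathreshold edges. Observed edges with uncorrected edgewise
#' `p < primary_threshold` form a graph whose connected components are the
#' candidate effects; their size (edge count by default, or summed
#' absolute t under `"intensity"`) is compared against the maximal
#' component size over `n_perm` random relabelings of subjects to groups.
#' Component-level `p_fwe = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param cohort A cohort tibble with `fc` list-column and `group` column.
#' @param primary_threshold Uncorrected two-sided p cutoff defining
#'   suprathreshold edges (default 0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @param component_stat `"extent"` (edge count, default) or
#'   `"intensity"` (sum of `|t|` over the component's edges).
#' @inheritParams edgewise_ttest
#' @return Object of class `nbs_result`: list with `edges` (the
#'   [edgewise_ttest()] tibble plus `suprathreshold` and `component_id`),
#'   `components` (tibble `component_id`, `n_edges`, `n_nodes`,
#'   `statistic`, `p_fwe`), `null_max` (length-`n_perm` numeric), and
#'   `params`. An absence of suprathreshold edges yields an empty
#'   `components` table, not an error.
#' @export
nbs <- function(cohort, primary_threshold = 0.05, n_perm = 1000, seed = 1L,
                component_stat = c("extent", "intensity"),
                use_fisher_z = TRUE, var_equal = TRUE) {
  component_stat <- match.arg(component_stat)
  stopifnot(primary_threshold > 0, primary_threshold < 1, n_perm >= 1)
  groups <- split_fc_groups(cohort)
  n_a <- length(groups$treated)
  n_b <- length(groups$control)
  stopifnot(n_a >= 2, n_b >= 2)
  stack <- edge_value_stack(c(groups$treated, groups$control), use_fisher_z)
  n_sub <- n_a + n_b
  idx <- attr(stack, "edge_index")
  n_nodes <- attr(stack, "n_nodes")

  observed <- edgewise_ttest(cohort, use_fisher_z, var_equal)
  observed$suprathreshold <- observed$p < primary_threshold
  observed$component_id <- NA_integer_
  sup <- which(observed$suprathreshold)
  comp_stat_of <- function(t_abs, comp_ids) {
    if (component_stat == "extent") tabulate(comp_ids)
    else as.numeric(tapply(t_abs, comp_ids, sum))
  }
  components <- tibble::tibble(component_id = integer(), n_edges = integer(),
                               n_nodes = integer(), statistic = numeric(),
                               p_fwe = numeric())
  if (length(sup) > 0) {
    cid <- edge_components(observed$roi_i[sup], observed$roi_j[sup], n_nodes)
    observed$component_id[sup] <- cid
    stat <- comp_stat_of(abs(observed$t[sup]), cid)
    components <- tibble::tibble(
      component_id = seq_along(stat),
      n_edges = as.integer(tabulate(cid)),
      n_nodes = vapply(seq_along(stat), function(c) {
        length(unique(c(observed$roi_i[sup][cid == c],
                        observed$roi_j[sup][cid == c])))
      }, integer(1)),
      statistic = stat
    )
  }

  # permutation null of the maximal component statistic
  null_max <- with_preserved_rng(seed, {
    assign <- t(vapply(seq_len(n_perm), function(...) {
      a <- numeric(n_sub)
      a[sample.int(n_sub, n_a)] <- 1
      a
    }, numeric(n_sub)))
    tp <- perm_tstats(stack, assign, n_a, n_b, var_equal)
    pp <- 2 * stats::pt(-abs(tp$t), tp$df)
    vapply(seq_len(n_perm), function(r) {
      s <- which(pp[r, ] < primary_threshold)
      if (length(s) == 0) return(0)
      cidp <- edge_components(idx[s, 1], idx[s, 2], n_nodes)
      max(comp_stat_of(abs(tp$t[r, s]), cidp))
    }, numeric(1))
  })

  if (nrow(components) > 0) {
    components$p_fwe <- vapply(components$statistic, function(s) {
      (1 + sum(null_max >= s)) / (1 + n_perm)
    }, numeric(1))
  }
  structure(
    list(edges = observed, components = components, null_max = null_max,
         params = list(primary_threshold = primary_threshold, n_perm = n_perm,
                       seed = seed, component_stat = component_stat,
                       use_fisher_z = use_fisher_z, var_equal = var_equal,
                       n_control = n_b, n_treated = n_a,
                       group_levels = groups$levels)),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d suprathreshold edges (p < %g), %d component(s), %d permutations\n",
              sum(x$edges$suprathreshold), x$params$primary_threshold,
              nrow(x$components), x$params$n_perm))
  if (nrow(x$components) > 0) print(x$components)
  invisible(x)
}

#' @describeIn nbs Edge-level table with component family-wise p-values.
#' @param x,object An `nbs_result`.
#' @param ... Unused.
#' @method tidy nbs_result
#' @export
tidy.nbs_result <- function(x, ...) {
  out <- x$edges
  if (nrow(x$components) > 0) {
    out <- dplyr::left_join(out,
                            x$components[, c("component_id", "p_fwe")],
                            by = "component_id")
  } else {
    out$p_fwe <- NA_real_
  }
  out
}

#' @describeIn nbs One-row summary (component count, smallest family-wise
#'   p, parameters).
#' @method glance nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    n_suprathreshold = sum(x$edges$suprathreshold),
    n_components = nrow(x$components),
    largest_component = if (nrow(x$components)) max(x$components$n_edges) else 0L,
    min_p_fwe = if (nrow(x$components)) min(x$components$p_fwe) else NA_real_,
    primary_threshold = x$params$primary_threshold,
    n_perm = x$params$n_perm
  )
}

#' Classify significant edges by cortical/subcortical node class
#'
#' @param edges A tibble with `roi_i`, `roi_j` (node indices), e.g. the
#'   significant rows of [tidy.nbs_result()]; or an `nbs_result`, in which
#'   case edges belonging to components with `p_fwe < alpha` are used.
#' @param roi_metadata Data frame with `index` and `class`
#'   (`"cortical"`/`"subcortical"`); defaults to [dmn_rois()].
#' @param alpha Component-level significance cutoff when an `nbs_result`
#'   is given (default 0.05).
#' @return Tibble with `class` (`cortico-cortical`, `cortico-subcortical`,
#'   `subcortico-subcortical`) and `n`; counts sum to the number of edges.
#' @export
classify_edges <- function(edges, roi_metadata = dmn_rois(), alpha = 0.05) {
  if (inherits(edges, "nbs_result")) {
    tb <- tidy.nbs_result(edges)
    edges <- tb[!is.na(tb$p_fwe) & tb$p_fwe < alpha, ]
  }
  stopifnot(is.data.frame(edges), all(c("roi_i", "roi_j") %in% names(edges)))
  cls <- roi_metadata$class[match(seq_len(max(roi_metadata$index)),
                                  roi_metadata$index)]
  lookup <- function(i) {
    out <- cls[i]
    if (anyNA(out) || any(!out %in% c("cortical", "subcortical"))) {
      stop("ROI index ", paste(i[is.na(out)], collapse = ", "),
           " has no cortical/subcortical class label", call. = FALSE)
    }
    out
  }
  levels <- c("cortico-cortical", "cortico-subcortical",
              "subcortico-subcortical")
  if (nrow(edges) == 0) {
    return(tibble::tibble(class = levels, n = 0L))
  }
  ci <- lookup(edges$roi_i)
  cj <- lookup(edges$roi_j)
  n_sub <- (ci == "subcortical") + (cj == "subcortical")
  cl <- levels[n_sub + 1]
  tibble::tibble(class = levels,
                 n = as.integer(table(factor(cl, levels = levels))))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`) with a
#' significance mask at the given q.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `p_fdr`, `significant`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(), p_fdr = numeric(),
                          significant = logical()))
  }
  stopifnot(all(p > 0), all(p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_fdr = adj, significant = adj < q)
}

#' Compare topology metrics between groups with FDR correction
#'
#' Two-sample t-tests per metric at each sparsity level and on the AUC
#' summaries, with Benjamini-Hochberg correction applied within metric
#' families: all global metrics (across sparsities and AUC) form one
#' family; nodal metrics form one family per sparsity level plus one for
#' the nodal AUCs.
#'
#' @param profiles A `topology_profiles` object with both groups (see
#'   [profile_cohort()]).
#' @param q FDR level (default 0.05).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @param metrics Global metrics to test (defaults to the efficiency,
#'   clustering, and path-length measures; the random-ensemble ratios are
#'   descriptive and not tested by default).
#' @return Tibble with `family`, `metric`, `sparsity` (`NA` for AUC rows),
#'   `node`, `label`, `mean_control`, `mean_treated`, `t`, `df`, `p`,
#'   `p_fdr`, `significant`. `t` is treated minus control.
#' @export
compare_topology <- function(profiles, q = 0.05, var_equal = TRUE,
                             metrics = c("e_glob", "e_loc", "c_p", "l_p")) {
  stopifnot(inherits(profiles, "topology_profiles"))
  long <- tidy.topology_profiles(profiles)
  keep_global <- long$metric %in% metrics & is.na(long$node)
  keep_nodal <- long$metric %in% c("e_nodal", "e_nodal_local", "c_i") &
    !is.na(long$node)
  df <- long[keep_global | keep_nodal, ]
  df$family <- dplyr::case_when(
    is.na(df$node) ~ "global",
    df$summary == "auc" ~ "nodal_auc",
    TRUE ~ paste0("nodal_s", format(df$sparsity, nsmall = 2))
  )
  grouped <- dplyr::group_by(df, .data$family, .data$metric, .data$summary,
                             .data$sparsity, .data$node, .data$label)
  res <- dplyr::summarise(
    grouped,
    mean_control = mean(.data$value[.data$group == "control"]),
    mean_treated = mean(.data$value[.data$group != "control"]),
    t = tryCatch(
      stats::t.test(.data$value[.data$group != "control"],
                    .data$value[.data$group == "control"],
                    var.equal = var_equal)$statistic,
      error = function(e) 0
    ),
    df = tryCatch(
      stats::t.test(.data$value[.data$group != "control"],
                    .data$value[.data$group == "control"],
                    var.equal = var_equal)$parameter,
      error = function(e) NA_real_
    ),
    p = tryCatch(
      stats::t.test(.data$value[.data$group != "control"],
                    .data$value[.data$group == "control"],
                    var.equal = var_equal)$p.value,
      error = function(e) 1
    ),
    .groups = "drop"
  )
  # zero variance in both groups -> no evidence, not an error
  res$t[!is.finite(res$t)] <- 0
  res$p[!is.finite(res$p)] <- 1
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$family),
    p_fdr = stats::p.adjust(.data$p, method = "BH")
  )
  res <- dplyr::ungroup(dplyr::mutate(res, significant = .data$p_fdr < q))
  dplyr::arrange(res, .data$family, .data$metric, .data$sparsity, .data$node)
}
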