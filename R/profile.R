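#' Topology profile of one subject across the sparsity sweep
#'
#' Thresholds the subject's FC matrix at each sparsity level (default
#' 0.10 to 0.50 in steps of 0.05, nine levels), computes every topology
#' metric plus small-world indices against a degree-preserving random
#' ensemble, and summarizes each metric by its trapezoidal area under the
#' curve (AUC) across sparsity.
#'
#' @param fc An `fc_matrix`.
#' @param sparsities Numeric vector of sparsity levels.
#' @param n_rand Random networks per sparsity level for gamma/lambda
#'   (default 100).
#' @param seed Integer seed; the profile is deterministic given
#'   `(fc, seed)`.
#' @param lambda_tol Passed to [small_worldness()].
#' @param negative_weights Passed to [threshold_by_sparsity()].
#' @param subject_id Identifier; defaults to the matrix's own.
#' @return Object of class `topology_profile`: list of tibbles `global`
#'   (subject_id, sparsity, metric, value), `nodal` (subject_id, sparsity,
#'   node, label, metric, value), `auc` (subject_id, metric, node, label,
#'   auc), plus `params`.
#' @export
profile_topology <- function(fc, sparsities = seq(0.10, 0.50, by = 0.05),
                             n_rand = 100, seed = 1L, lambda_tol = 0.15,
                             negative_weights = "zero",
                             subject_id = attr(fc, "subject_id")) {
  stopifnot(length(sparsities) >= 1, !is.unsorted(sparsities))
  if (is.null(subject_id)) subject_id <- NA_character_
  glob <- vector("list", length(sparsities))
  noda <- vector("list", length(sparsities))
  with_preserved_rng(seed, {
    for (k in seq_along(sparsities)) {
      net <- threshold_by_sparsity(fc, sparsities[k],
                                   negative_weights = negative_weights)
      met <- network_metrics(net)
      sw <- small_worldness(net, n_rand = n_rand, lambda_tol = lambda_tol)
      g <- dplyr::bind_cols(met$global,
                            sw[, c("c_p_rand", "l_p_rand", "gamma", "lambda",
                                   "sigma", "small_world")])
      glob[[k]] <- tidyr::pivot_longer(
        dplyr::mutate(g, small_world = as.numeric(.data$small_world)),
        -"sparsity", names_to = "metric", values_to = "value"
      )
      noda[[k]] <- tidyr::pivot_longer(
        dplyr::mutate(met$nodal, sparsity = sparsities[k],
                      degree = as.numeric(.data$degree)),
        c("degree", "e_nodal", "e_nodal_local", "c_i"),
        names_to = "metric", values_to = "value"
      )
    }
  })
  global <- dplyr::bind_rows(glob)
  global$subject_id <- subject_id
  global <- global[, c("subject_id", "sparsity", "metric", "value")]
  nodal <- dplyr::bind_rows(noda)
  nodal$subject_id <- subject_id
  nodal <- nodal[, c("subject_id", "sparsity", "node", "label", "metric",
                     "value")]
  auc <- dplyr::bind_rows(
    dplyr::summarise(
      dplyr::group_by(global, .data$subject_id, .data$metric),
      node = NA_integer_, label = NA_character_,
      auc = trapezoid_auc(.data$sparsity, .data$value), .groups = "drop"
    ),
    dplyr::summarise(
      dplyr::group_by(nodal, .data$subject_id, .data$metric, .data$node,
                      .data$label),
      auc = trapezoid_auc(.data$sparsity, .data$value), .groups = "drop"
    )
  )
  structure(
    list(global = global, nodal = nodal, auc = auc,
         params = list(sparsities = sparsities, n_rand = n_rand, seed = seed,
                       lambda_tol = lambda_tol,
                       negative_weights = negative_weights)),
    class = "topology_profile"
  )
}

trapezoid_auc <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  ok <- is.finite(y)
  if (sum(ok) < 2) return(NA_real_)
  pracma::trapz(x[ok], y[ok])
}

#' @export
print.topology_profile <- function(x, ...) {
  cat(sprintf("<topology_profile> subject %s: %d sparsity levels, %d metrics\n",
              x$global$subject_id[1], length(x$params$sparsities),
              length(unique(x$global$metric))))
  invisible(x)
}

#' Topology profiles for every kept subject of a cohort
#'
#' @param cohort A cohort tibble with an `fc` list-column (see
#'   [compute_cohort_fc()]).
#' @inheritParams profile_topology
#' @param seed Base seed; subject `k` uses `seed + k` so profiles are
#'   independent but reproducible.
#' @return Object of class `topology_profiles`: tibbles `global`, `nodal`,
#'   `auc` (each with `subject_id` and `group` columns) plus `params`.
#' @export
profile_cohort <- function(cohort, sparsities = seq(0.10, 0.50, by = 0.05),
                           n_rand = 100, seed = 1L, lambda_tol = 0.15,
                           negative_weights = "zero") {
  stopifnot(is.data.frame(cohort), "fc" %in% names(cohort))
  rows <- which(!vapply(cohort$fc, is.null, logical(1)))
  profs <- lapply(seq_along(rows), function(k) {
    i <- rows[k]
    p <- profile_topology(cohort$fc[[i]], sparsities, n_rand,
                          seed = seed + k, lambda_tol = lambda_tol,
                          negative_weights = negative_weights,
                          subject_id = cohort$subject_id[i])
    lapply(p[c("global", "nodal", "auc")], function(tb) {
      tb$group <- cohort$group[i]
      tb
    })
  })
  out <- list(
    global = dplyr::bind_rows(lapply(profs, `[[`, "global")),
    nodal = dplyr::bind_rows(lapply(profs, `[[`, "nodal")),
    auc = dplyr::bind_rows(lapply(profs, `[[`, "auc")),
    params = list(sparsities = sparsities, n_rand = n_rand, seed = seed,
                  lambda_tol = lambda_tol,
                  negative_weights = negative_weights)
  )
  structure(out, class = "topology_profiles")
}

#' @export
print.topology_profiles <- function(x, ...) {
  cat(sprintf("<topology_profiles> %d subjects (%s)\n",
              length(unique(x$global$subject_id)),
              paste(names(table(unique(x$global[c("subject_id", "group")])$group)),
                    table(unique(x$global[c("subject_id", "group")])$group),
                    collapse = ", ", sep = ": ")))
  invisible(x)
}

#' Tidy topology profiles into one long tibble
#'
#' @param x A `topology_profiles` (or `topology_profile`) object.
#' @param ... Unused.
#' @return Long tibble with columns `subject_id`, `group` (if present),
#'   `sparsity` (`NA` for AUC rows), `summary` (`"value"` or `"auc"`),
#'   `node`, `label`, `metric`, `value`.
#' @method tidy topology_profiles
#' @export
tidy.topology_profiles <- function(x, ...) {
  g <- dplyr::mutate(x$global, node = NA_integer_, label = NA_character_,
                     summary = "value")
  n <- dplyr::mutate(x$nodal, summary = "value")
  a <- dplyr::mutate(dplyr::rename(x$auc, value = "auc"),
                     sparsity = NA_real_, summary = "auc")
  cols <- intersect(c("subject_id", "group", "sparsity", "summary", "node",
                      "label", "metric", "value"),
                    union(names(g), names(a)))
  dplyr::bind_rows(g[intersect(cols, names(g))], n[intersect(cols, names(n))],
                   a[intersect(cols, names(a))])[, cols]
}

#' @method tidy topology_profile
#' @export
tidy.topology_profile <- function(x, ...) tidy.topology_profiles(x, ...)

#' Group-mean topology metrics across the sparsity sweep
#'
#' @param object A `topology_profiles` object.
#' @param metrics Which global metrics to show.
#' @param ... Unused.
#' @return A ggplot: mean with standard-error ribbon per group, one facet
#'   per metric.
#' @method autoplot topology_profiles
#' @export
autoplot.topology_profiles <- function(object,
                                       metrics = c("e_glob", "e_loc", "c_p",
                                                   "l_p", "gamma", "lambda"),
                                       ...) {
  df <- dplyr::filter(object$global, .data$metric %in% metrics)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$sparsity, .data$metric),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sparsity, y = .data$mean,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "metric value") +
    ggplot2::theme_minimal()
}
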