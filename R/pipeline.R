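#' Run the full resting-state connectivity analysis
#'
#' End-to-end orchestration: generate (or accept) a cohort, preprocess
#' (motion QC, detrend, band-pass, nuisance regression), compute FC
#' matrices, run the NBS group comparison with edge classification, sweep
#' the sparsity grid for topology profiles, and compare topology metrics
#' between groups with FDR correction.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built `dmn_cohort` (e.g. from
#'   [read_cohort()]); when `NULL`, one is generated from `config`.
#' @param tr_seconds Repetition time for cohorts read from disk.
#' @param sparsities Sparsity sweep (default 0.10-0.50 by 0.05).
#' @param n_rand Random networks per sparsity for gamma/lambda.
#' @param nbs_threshold NBS primary (edge-level) p threshold.
#' @param n_perm NBS permutations (default 1000).
#' @param fdr_q FDR level for topology comparisons.
#' @param seed Seed for NBS permutations and topology-profile ensembles;
#'   defaults to the config's seed.
#' @param lambda_tol Small-world lambda tolerance.
#' @return Object of class `dmn_report`: list with `cohort` (with `fc`),
#'   `qc` (per-subject QC tibble), `nbs` ([nbs()] result), `edge_classes`
#'   ([classify_edges()] counts over significant edges), `profiles`
#'   ([profile_cohort()]), `topology` ([compare_topology()] table),
#'   `small_world` (per group x sparsity: fraction of subjects classified
#'   small-world), and `params` (everything needed to reproduce the run).
#' @examples
#' \donttest{
#' report <- run_dmn_pipeline(cohort_config(n_control = 6, n_treated = 6, seed = 2),
#'                            n_rand = 20, n_perm = 100)
#' glance(report)
#' }
#' @export
run_dmn_pipeline <- function(config = cohort_config(), cohort = NULL,
                             tr_seconds = NULL,
                             sparsities = seq(0.10, 0.50, by = 0.05),
                             n_rand = 100, nbs_threshold = 0.05,
                             n_perm = 1000, fdr_q = 0.05, seed = NULL,
                             lambda_tol = 0.15) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  if (is.null(seed)) {
    seed <- if (!is.null(attr(cohort, "config"))) attr(cohort, "config")$seed else 1L
  }
  pre <- preprocess_cohort(cohort, tr_seconds = tr_seconds)
  fc <- compute_cohort_fc(pre)
  qc <- fc[, c("subject_id", "group", "kept", "max_abs_translation_mm",
               "max_abs_rotation_deg")]
  nbs_res <- nbs(fc, primary_threshold = nbs_threshold, n_perm = n_perm,
                 seed = seed)
  n_rois <- nrow(fc$fc[[which(!vapply(fc$fc, is.null, logical(1)))[1]]])
  edge_classes <- if (n_rois == 12) classify_edges(nbs_res) else NULL
  profiles <- profile_cohort(fc, sparsities = sparsities, n_rand = n_rand,
                             seed = seed, lambda_tol = lambda_tol)
  topology <- compare_topology(profiles, q = fdr_q)
  sw <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(profiles$global, .data$metric == "small_world"),
      .data$group, .data$sparsity
    ),
    fraction_small_world = mean(.data$value), .groups = "drop"
  )
  structure(
    list(cohort = fc, qc = qc, nbs = nbs_res, edge_classes = edge_classes,
         profiles = profiles, topology = topology, small_world = sw,
         params = list(
           sparsities = sparsities, n_rand = n_rand,
           nbs_threshold = nbs_threshold, n_perm = n_perm, fdr_q = fdr_q,
           seed = seed, lambda_tol = lambda_tol,
           preprocess = attr(pre, "preprocess_params"),
           config = attr(cohort, "config")
         )),
    class = "dmn_report"
  )
}

#' @export
print.dmn_report <- function(x, ...) {
  cat("<dmn_report>\n")
  cat(sprintf("  subjects: %d kept / %d total\n", sum(x$qc$kept), nrow(x$qc)))
  ncomp <- nrow(x$nbs$components)
  sig <- if (ncomp) sum(x$nbs$components$p_fwe < x$params$fdr_q) else 0L
  cat(sprintf("  NBS: %d component(s), %d significant at p_fwe < %g (%d permutations)\n",
              ncomp, sig, x$params$fdr_q, x$params$n_perm))
  cat(sprintf("  topology: %d of %d tests significant after FDR\n",
              sum(x$topology$significant), nrow(x$topology)))
  invisible(x)
}

#' @describeIn run_dmn_pipeline One-row run summary.
#' @param x,object A `dmn_report`.
#' @param ... Unused.
#' @method glance dmn_report
#' @export
glance.dmn_report <- function(x, ...) {
  ncomp <- nrow(x$nbs$components)
  tibble::tibble(
    n_subjects = nrow(x$qc), n_kept = sum(x$qc$kept),
    n_excluded = sum(!x$qc$kept),
    n_nbs_components = ncomp,
    n_nbs_significant = if (ncomp) sum(x$nbs$components$p_fwe < x$params$fdr_q) else 0L,
    largest_component_edges = if (ncomp) max(x$nbs$components$n_edges) else 0L,
    min_p_fwe = if (ncomp) min(x$nbs$components$p_fwe) else NA_real_,
    n_topology_significant = sum(x$topology$significant),
    seed = x$params$seed
  )
}

#' Write a pipeline report's tables and provenance to disk
#'
#' Emits plain-text artifacts sufficient to regenerate the run: the QC
#' table, edge-level NBS table, component table, topology comparison
#' table, small-world summary, edge-class counts, and a JSON file with
#' every parameter (including the cohort configuration and all seeds).
#'
#' @param report A `dmn_report`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "dmn_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(directory, name))
  }
  w(report$qc, "qc.csv")
  w(tidy.nbs_result(report$nbs), "nbs_edges.csv")
  w(report$nbs$components, "nbs_components.csv")
  w(report$topology, "topology_tests.csv")
  w(report$small_world, "small_world.csv")
  if (!is.null(report$edge_classes)) w(report$edge_classes, "edge_classes.csv")
  w(tidy.topology_profiles(report$profiles), "topology_profiles.csv")
  params <- report$params
  params$config$base_correlation <- unclass(params$config$base_correlation)
  params$config$treated_correlation <- unclass(params$config$treated_correlation)
  jsonlite::write_json(params, file.path(directory, "run_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(directory)
}
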