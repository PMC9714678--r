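#' Default base correlation structure for a synthetic DMN cohort
#'
#' Builds a plausible resting-state ROI-ROI correlation target: homotopic
#' (left-right) pairs correlate strongly, all other pairs at a weaker
#' background level. A small symmetric jitter breaks exact ties between
#' edges, and the result is projected to the nearest positive-semidefinite
#' correlation matrix.
#'
#' @param n_rois Number of ROIs (nodes). Homotopic pairs are `(1,2)`,
#'   `(3,4)`, ... so an even count is expected for the homotopic structure
#'   to be meaningful.
#' @param homotopic Target correlation for left-right pairs of the same
#'   region (default 0.6).
#' @param background Target correlation for all other pairs (default 0.3).
#' @param jitter_sd Standard deviation of the symmetric Gaussian jitter
#'   added to off-diagonal entries (default 0.03). Set to 0 for an exact
#'   block structure.
#' @param seed Integer seed for the jitter (the global RNG state is left
#'   untouched).
#' @return An `n_rois` x `n_rois` correlation matrix (symmetric, unit
#'   diagonal, positive semidefinite).
#' @examples
#' R <- default_base_correlation(12)
#' R[1, 2]  # homotopic auditory pair, ~0.6
#' @export
default_base_correlation <- function(n_rois = 12, homotopic = 0.6,
                                     background = 0.3, jitter_sd = 0.03,
                                     seed = 1L) {
  stopifnot(n_rois >= 2)
  R <- matrix(background, n_rois, n_rois)
  for (k in seq_len(n_rois %/% 2)) {
    i <- 2 * k - 1
    R[i, i + 1] <- R[i + 1, i] <- homotopic
  }
  if (jitter_sd > 0) {
    jit <- with_preserved_rng(seed, {
      J <- matrix(stats::rnorm(n_rois^2, sd = jitter_sd), n_rois, n_rois)
      (J + t(J)) / 2
    })
    R <- R + jit
  }
  R[R > 0.99] <- 0.99
  R[R < -0.99] <- -0.99
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  dimnames(R) <- NULL
  R
}

#' Configure a synthetic two-group cohort
#'
#' Describes a cohort of `n_control` + `n_treated` subjects, each with a
#' T x N ROI BOLD time-series matrix and a T x 6 motion-parameter trace.
#' Control subjects are generated from `base_correlation`; treated subjects
#' from the same matrix with `planted_edges` deltas applied, so the
#' between-group difference is known exactly.
#'
#' Defaults mirror the acquisition this pipeline targets: 180 volumes at
#' TR = 2 s over 12 DMN ROIs, with 12 subjects per group.
#'
#' @param n_control,n_treated Subjects per group.
#' @param n_rois Number of ROIs (default 12).
#' @param n_volumes Time points per subject (default 180). Must be at least
#'   `2 * n_rois` so sample correlations are well defined.
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param base_correlation N x N target correlation matrix (symmetric, unit
#'   diagonal, positive semidefinite).
#' @param planted_edges `NULL`, or a data frame with columns `roi_i`,
#'   `roi_j`, `delta_r`: correlation deltas added to the treated group's
#'   target matrix. The resulting matrix must remain positive semidefinite.
#' @param drift_slope_sd SD of the per-ROI linear drift slope, in signal
#'   units per volume (default 0.002; the signal has unit variance).
#' @param noise_sd SD of additive white measurement noise (default 0.25).
#' @param motion_excursion_prob Probability that a subject's motion trace
#'   contains an above-threshold excursion (> 1 mm or > 1 degree),
#'   default 0.15.
#' @param roi_labels Character vector of ROI names; defaults to the DMN
#'   short forms when `n_rois == 12`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()]
#' @examples
#' cfg <- cohort_config(n_control = 4, n_treated = 4, seed = 7)
#' cfg$n_volumes
#' @export
cohort_config <- function(n_control = 12, n_treated = 12, n_rois = 12,
                          n_volumes = 180, tr_seconds = 2,
                          base_correlation = default_base_correlation(n_rois),
                          planted_edges = NULL,
                          drift_slope_sd = 0.002, noise_sd = 0.25,
                          motion_excursion_prob = 0.15,
                          roi_labels = default_roi_labels(n_rois),
                          seed = 1L) {
  stopifnot(
    n_control >= 1, n_treated >= 1, n_rois >= 2,
    tr_seconds > 0, drift_slope_sd >= 0, noise_sd >= 0,
    motion_excursion_prob >= 0, motion_excursion_prob <= 1,
    length(roi_labels) == n_rois, !anyDuplicated(roi_labels)
  )
  if (n_volumes < 2 * n_rois) {
    stop("`n_volumes` must be at least 2 * `n_rois` (got ", n_volumes,
         " volumes for ", n_rois, " ROIs)", call. = FALSE)
  }
  check_correlation_matrix(base_correlation, n_rois, what = "base_correlation")
  treated_correlation <- apply_planted_edges(base_correlation, planted_edges)
  structure(
    list(
      n_control = as.integer(n_control), n_treated = as.integer(n_treated),
      n_rois = as.integer(n_rois), n_volumes = as.integer(n_volumes),
      tr_seconds = tr_seconds,
      base_correlation = base_correlation,
      treated_correlation = treated_correlation,
      planted_edges = planted_edges,
      drift_slope_sd = drift_slope_sd, noise_sd = noise_sd,
      motion_excursion_prob = motion_excursion_prob,
      roi_labels = as.character(roi_labels),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d control + %d treated subjects; %d ROIs x %d volumes @ TR %g s\n",
              x$n_control, x$n_treated, x$n_rois, x$n_volumes, x$tr_seconds))
  n_pe <- if (is.null(x$planted_edges)) 0L else nrow(x$planted_edges)
  cat(sprintf("  planted edges: %d; noise_sd %g; drift_slope_sd %g; excursion prob %g; seed %d\n",
              n_pe, x$noise_sd, x$drift_slope_sd, x$motion_excursion_prob, x$seed))
  invisible(x)
}

# Symmetry / unit diagonal / PSD check, with an informative error.
check_correlation_matrix <- function(R, n_rois, what = "correlation matrix",
                                     tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != n_rois || ncol(R) != n_rois) {
    stop("`", what, "` must be a ", n_rois, " x ", n_rois, " matrix",
         call. = FALSE)
  }
  if (max(abs(R - t(R))) > tol) {
    stop("`", what, "` must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > tol) {
    stop("`", what, "` must have a unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("`", what, "` is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Apply planted deltas one edge at a time so a PSD failure can name the
# offending edge.
apply_planted_edges <- function(R, planted_edges, tol = 1e-8) {
  if (is.null(planted_edges) || nrow(planted_edges) == 0) return(R)
  pe <- as.data.frame(planted_edges)
  if (!all(c("roi_i", "roi_j", "delta_r") %in% names(pe))) {
    stop("`planted_edges` needs columns roi_i, roi_j, delta_r", call. = FALSE)
  }
  n <- nrow(R)
  for (k in seq_len(nrow(pe))) {
    i <- pe$roi_i[k]; j <- pe$roi_j[k]; d <- pe$delta_r[k]
    if (i < 1 || i > n || j < 1 || j > n || i == j) {
      stop("planted edge (", i, ", ", j, ") is not a valid off-diagonal pair",
           call. = FALSE)
    }
    R[i, j] <- R[i, j] + d
    R[j, i] <- R[i, j]
    if (abs(R[i, j]) > 1) {
      stop("planted edge (", i, ", ", j, ") pushes the correlation to ",
           format(R[i, j]), ", outside [-1, 1]", call. = FALSE)
    }
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -tol) {
      stop("treated-group target matrix loses positive semidefiniteness at ",
           "planted edge (", i, ", ", j, ") with delta_r = ", d,
           " (min eigenvalue ", format(ev), ")", call. = FALSE)
    }
  }
  R
}

# Run `expr` under a fixed seed, then restore the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
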