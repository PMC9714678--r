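#' Motion-based subject quality control
#'
#' A subject is kept only if every translation sample is within
#' `max_translation_mm` on each axis and every rotation sample is within
#' `max_rotation_deg` on each axis. Defaults are the conventional rodent
#' rs-fMRI exclusion criteria of 1 mm and 1 degree. QC never alters data;
#' it only includes or excludes whole subjects.
#'
#' @param motion T x 6 motion matrix (columns `tx_mm` ... `rz_deg`) as
#'   produced by [generate_cohort()] or [read_motion_tsv()].
#' @param max_translation_mm,max_rotation_deg Exclusion thresholds.
#' @param subject_id Optional identifier carried into the result.
#' @return A one-row tibble: `subject_id`, `kept`,
#'   `max_abs_translation_mm`, `max_abs_rotation_deg`.
#' @examples
#' qc_motion(matrix(0, 10, 6, dimnames = list(NULL,
#'   c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg"))))
#' @export
qc_motion <- function(motion, max_translation_mm = 1, max_rotation_deg = 1,
                      subject_id = NA_character_) {
  stopifnot(is.matrix(motion), ncol(motion) == 6, nrow(motion) >= 1,
            !anyNA(motion))
  max_t <- max(abs(motion[, 1:3]))
  max_r <- max(abs(motion[, 4:6]))
  tibble::tibble(
    subject_id = subject_id,
    kept = max_t <= max_translation_mm && max_r <= max_rotation_deg,
    max_abs_translation_mm = max_t,
    max_abs_rotation_deg = max_r
  )
}

#' Remove a linear trend from each column
#'
#' Ordinary least-squares fit of `intercept + slope * time` per column,
#' subtracted; output columns are orthogonal to both the constant and the
#' linear ramp. Idempotent, and exact for inputs that are exactly linear
#' (constant columns become zero).
#'
#' @param x T x N numeric matrix (T >= 3).
#' @return Matrix of the same shape (column names preserved).
#' @export
detrend_linear <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 3, !anyNA(x))
  X <- cbind(1, seq_len(nrow(x)))
  r <- stats::lm.fit(X, x)$residuals
  dimnames(r) <- dimnames(x)
  r
}

#' Zero-phase band-pass filter for ROI time series
#'
#' Butterworth filter of the given order applied forward and backward
#' (`signal::filtfilt`), so features are not shifted in time. The default
#' band 0.01-0.08 Hz isolates the low-frequency BOLD fluctuations used for
#' resting-state connectivity; at TR = 2 s the Nyquist frequency is
#' 0.25 Hz.
#'
#' @param x T x N numeric matrix.
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)`.
#' @param order Butterworth order (default 2; doubled in effect by the
#'   forward-backward pass).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, tr_seconds, low_hz = 0.01, high_hz = 0.08,
                            order = 2) {
  stopifnot(is.matrix(x), !anyNA(x), tr_seconds > 0)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop("band [", low_hz, ", ", high_hz, "] Hz must lie strictly inside (0, ",
         nyquist, ") Hz (Nyquist for TR = ", tr_seconds, " s)", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- apply(x, 2, function(col) as.numeric(signal::filtfilt(bf, col)))
  dimnames(out) <- dimnames(x)
  out
}

#' Regress motion parameters out of ROI time series
#'
#' Per ROI column, returns the residual of an OLS regression on an
#' intercept plus the six realignment parameters. Residuals are orthogonal
#' to every retained regressor. Degenerate (constant or all-zero) motion
#' columns are dropped with a warning, so an all-zero motion trace reduces
#' to mean-centering.
#'
#' @param x T x N numeric matrix.
#' @param motion T x 6 motion matrix with the same number of rows.
#' @return Residual matrix of the same shape as `x`.
#' @export
regress_nuisance <- function(x, motion) {
  stopifnot(is.matrix(x), is.matrix(motion), nrow(x) == nrow(motion),
            ncol(motion) == 6, !anyNA(x), !anyNA(motion))
  keep <- apply(motion, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("dropping ", sum(!keep),
            " constant motion regressor(s) from the nuisance design",
            call. = FALSE)
  }
  X <- cbind(1, motion[, keep, drop = FALSE])
  qrX <- qr(X)
  r <- qr.resid(qrX, x)
  dimnames(r) <- dimnames(x)
  r
}

#' Preprocess one subject: QC, detrend, band-pass, motion regression
#'
#' Applies the temporal pipeline in the fixed order: motion QC (exclude the
#' whole subject on any excursion beyond the thresholds), linear
#' detrending, zero-phase band-pass filtering, then nuisance regression of
#' the six motion parameters.
#'
#' @param timeseries T x N numeric matrix.
#' @param motion T x 6 motion matrix (same T).
#' @inheritParams qc_motion
#' @inheritParams bandpass_filter
#' @param subject_id Optional identifier.
#' @return A list with `qc` (the [qc_motion()] row) and `timeseries` (the
#'   processed matrix for kept subjects, `NULL` for excluded ones).
#' @export
preprocess_subject <- function(timeseries, motion, tr_seconds,
                               low_hz = 0.01, high_hz = 0.08, order = 2,
                               max_translation_mm = 1, max_rotation_deg = 1,
                               subject_id = NA_character_) {
  stopifnot(nrow(timeseries) == nrow(motion))
  qc <- qc_motion(motion, max_translation_mm, max_rotation_deg, subject_id)
  if (!qc$kept) {
    return(list(qc = qc, timeseries = NULL))
  }
  out <- detrend_linear(timeseries)
  out <- bandpass_filter(out, tr_seconds, low_hz, high_hz, order)
  out <- regress_nuisance(out, motion)
  list(qc = qc, timeseries = out)
}

#' Preprocess every subject in a cohort
#'
#' Cohort-level verb around [preprocess_subject()]. Subjects failing motion
#' QC keep their row but get `kept = FALSE` and an unmodified time series;
#' downstream verbs operate on kept subjects only.
#'
#' @param cohort A `dmn_cohort` tibble.
#' @param tr_seconds Repetition time; defaults to the cohort config's value
#'   when the cohort was generated in-session, else must be given.
#' @inheritParams preprocess_subject
#' @return The cohort tibble with added columns `kept`,
#'   `max_abs_translation_mm`, `max_abs_rotation_deg`, and `timeseries`
#'   replaced by its preprocessed version for kept subjects.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 2, n_treated = 2, seed = 1))
#' preprocess_cohort(cohort)
#' @export
preprocess_cohort <- function(cohort, tr_seconds = NULL,
                              low_hz = 0.01, high_hz = 0.08, order = 2,
                              max_translation_mm = 1, max_rotation_deg = 1) {
  stopifnot(is.data.frame(cohort))
  if (is.null(tr_seconds)) {
    cfg <- attr(cohort, "config")
    if (is.null(cfg)) stop("`tr_seconds` must be supplied for cohorts read from disk",
                           call. = FALSE)
    tr_seconds <- cfg$tr_seconds
  }
  res <- purrr::map2(cohort$timeseries, cohort$motion, function(ts, mo) {
    preprocess_subject(ts, mo, tr_seconds, low_hz, high_hz, order,
                       max_translation_mm, max_rotation_deg)
  })
  qc <- dplyr::bind_rows(purrr::map(res, "qc"))
  out <- cohort
  out$kept <- qc$kept
  out$max_abs_translation_mm <- qc$max_abs_translation_mm
  out$max_abs_rotation_deg <- qc$max_abs_rotation_deg
  out$timeseries <- purrr::map2(res, cohort$timeseries, function(r, orig) {
    if (is.null(r$timeseries)) orig else r$timeseries
  })
  attr(out, "preprocess_params") <- list(
    tr_seconds = tr_seconds, low_hz = low_hz, high_hz = high_hz,
    order = order, max_translation_mm = max_translation_mm,
    max_rotation_deg = max_rotation_deg
  )
  out
}
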