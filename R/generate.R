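#' Generate a synthetic two-group cohort of ROI BOLD time series
#'
#' Draws `n_control + n_treated` subjects from a [cohort_config()]. Each
#' subject's signal is built from band-limited (0.01-0.08 Hz) Gaussian
#' innovations that are empirically whitened and mixed by the Cholesky
#' factor of the group's target correlation matrix, so the noise-free
#' sample correlation of the generated series equals the stored
#' `ground_truth_r` exactly; per-ROI linear drift and white measurement
#' noise are then added. Motion traces are smooth bounded random walks,
#' with an above-threshold excursion (> 1 mm or > 1 degree) injected with
#' probability `motion_excursion_prob`.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `dmn_cohort` with one row per subject and
#'   columns `subject_id`, `group` (`"control"`/`"treated"`), `timeseries`
#'   (list of T x N matrices with ROI column names), `motion` (list of
#'   T x 6 matrices, columns `tx_mm`, `ty_mm`, `tz_mm`, `rx_deg`,
#'   `ry_deg`, `rz_deg`), `has_excursion` (logical ground truth), and
#'   `ground_truth_r` (list of N x N target correlation matrices).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 3, n_treated = 3, seed = 1))
#' cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- c(rep("control", config$n_control), rep("treated", config$n_treated))
  n <- length(groups)
  ids <- sprintf("sub-%s%02d", ifelse(groups == "control", "c", "t"),
                 c(seq_len(config$n_control), seq_len(config$n_treated)))
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    target <- if (groups[k] == "control") config$base_correlation else config$treated_correlation
    ts <- generate_timeseries(config, target)
    colnames(ts) <- config$roi_labels
    excursion <- stats::runif(1) < config$motion_excursion_prob
    motion <- generate_motion(config$n_volumes, excursion)
    rows[[k]] <- tibble::tibble(
      subject_id = ids[k], group = groups[k],
      timeseries = list(ts), motion = list(motion),
      has_excursion = excursion, ground_truth_r = list(target)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("dmn_cohort", class(out))
  out
}

#' @export
print.dmn_cohort <- function(x, ...) {
  cat(sprintf("<dmn_cohort> %d subjects (%d control, %d treated)\n",
              nrow(x), sum(x$group == "control"), sum(x$group == "treated")))
  NextMethod()
}

# One subject's T x N series: whitened band-limited innovations mixed by
# chol(target), plus linear drift and white noise.
generate_timeseries <- function(config, target) {
  T_ <- config$n_volumes; N <- config$n_rois
  E <- matrix(stats::rnorm(T_ * N), T_, N)
  E <- fft_bandpass(E, config$tr_seconds, 0.01, 0.08)
  # empirical whitening: sample covariance of the innovations becomes
  # exactly the identity, so mixing yields sample correlation == target
  E <- scale(E, center = TRUE, scale = FALSE)
  W <- chol(crossprod(E) / (T_ - 1))
  E <- E %*% backsolve(W, diag(N))
  L <- chol_psd(target)
  S <- E %*% L
  drift <- outer(seq_len(T_) - 1,
                 stats::rnorm(N, sd = config$drift_slope_sd))
  noise <- matrix(stats::rnorm(T_ * N, sd = config$noise_sd), T_, N)
  S + drift + noise
}

# Cholesky-like factor for a PSD (possibly rank-deficient) matrix.
chol_psd <- function(R, tol = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

# Ideal zero-phase frequency-domain band-pass used only for generation
# (preprocessing uses the Butterworth realization in bandpass_filter()).
fft_bandpass <- function(x, tr_seconds, low_hz, high_hz) {
  T_ <- nrow(x)
  freq <- (seq_len(T_) - 1) / (T_ * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)  # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / T_
}

# Smooth bounded random-walk motion trace; optional injected excursion
# guaranteed to exceed 1 mm (translation) or 1 degree (rotation).
generate_motion <- function(n_volumes, excursion) {
  walk <- function(max_amp) {
    w <- cumsum(stats::rnorm(n_volumes))
    w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
    w[is.na(w)] <- 0
    peak <- max(abs(w))
    if (peak > 0) w <- w / peak * max_amp
    as.numeric(w)
  }
  amps <- stats::runif(6, 0.05, 0.6)  # clean traces stay well below 1
  m <- vapply(amps, walk, numeric(n_volumes))
  colnames(m) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  if (excursion) {
    axis <- sample.int(6, 1)
    t0 <- sample(seq(10, n_volumes - 10), 1)
    target <- sample(c(-1, 1), 1) * stats::runif(1, 1.1, 1.8)
    bump <- (target - m[t0, axis]) * exp(-((seq_len(n_volumes) - t0)^2) / 18)
    m[, axis] <- m[, axis] + bump
  }
  m
}
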