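#' Pearson functional-connectivity matrix
#'
#' Edge weight `w[i, j]` is the Pearson correlation between ROI columns
#' `i` and `j` of the (preprocessed) time series. The diagonal is set to
#' zero: self-connections carry no information and would otherwise give
#' zero-length edges under the `1 - w` distance transform.
#'
#' @param x T x N numeric matrix with ROI column names (or a bare matrix).
#' @param subject_id Optional identifier stored as an attribute.
#' @return An `fc_matrix`: N x N symmetric numeric matrix, values in
#'   `[-1, 1]` off-diagonal, zero diagonal, ROI labels as dimnames.
#' @examples
#' set.seed(1)
#' compute_fc(matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c"))))
#' @export
compute_fc <- function(x, subject_id = NA_character_) {
  stopifnot(is.matrix(x), nrow(x) >= 3, ncol(x) >= 2, !anyNA(x))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time series for ROI ", paste(bad, collapse = ", "),
         ": correlation undefined (degenerate preprocessing?)", call. = FALSE)
  }
  w <- stats::cor(x)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  structure(w, class = c("fc_matrix", "matrix", "array"),
            subject_id = subject_id)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d ROIs, subject %s\n", nrow(x),
              attr(x, "subject_id")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Fisher z-transform of a connectivity matrix
#'
#' `atanh(w)` entrywise off the diagonal, for variance stabilization in
#' edgewise t-tests. Correlations are clipped to `|w| <= 1 - 1e-12` first
#' so degenerate inputs (duplicated columns) do not produce infinities.
#'
#' @param fc An `fc_matrix` or plain correlation matrix.
#' @return Matrix of z-values with zero diagonal.
#' @export
fisher_z <- function(fc) {
  w <- unclass(fc)
  w <- pmin(pmax(w, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(w)
  diag(z) <- 0
  z
}

#' Add functional-connectivity matrices to a cohort
#'
#' Cohort-level verb: computes [compute_fc()] for every kept subject and
#' stores it in a new `fc` list-column (`NULL` for excluded subjects).
#'
#' @param cohort A `dmn_cohort` tibble, normally after
#'   [preprocess_cohort()]. If no `kept` column exists, all subjects are
#'   used.
#' @return The cohort with an added `fc` list-column.
#' @export
compute_cohort_fc <- function(cohort) {
  stopifnot(is.data.frame(cohort), "timeseries" %in% names(cohort))
  kept <- if ("kept" %in% names(cohort)) cohort$kept else rep(TRUE, nrow(cohort))
  out <- cohort
  out$fc <- purrr::pmap(list(cohort$timeseries, kept, cohort$subject_id),
                        function(ts, k, id) {
                          if (!k) NULL else compute_fc(ts, subject_id = id)
                        })
  out
}

#' Tidy a connectivity matrix into an edge list
#'
#' @param x An `fc_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered ROI pair: `roi_i`, `roi_j`,
#'   `label_i`, `label_j`, `weight`.
#' @method tidy fc_matrix
#' @export
tidy.fc_matrix <- function(x, ...) {
  w <- unclass(x)
  n <- nrow(w)
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  idx <- which(upper.tri(w), arr.ind = TRUE)
  tibble::tibble(
    roi_i = idx[, 1], roi_j = idx[, 2],
    label_i = labels[idx[, 1]], label_j = labels[idx[, 2]],
    weight = w[idx]
  )
}

#' Heatmap of a connectivity matrix
#'
#' @param object An `fc_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_matrix
#' @export
autoplot.fc_matrix <- function(object, ...) {
  df <- tidy.fc_matrix(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, label_i = "label_j", label_j = "label_i")
  )
  labels <- rownames(object)
  df2$label_i <- factor(df2$label_i, levels = labels)
  df2$label_j <- factor(df2$label_j, levels = rev(labels))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$label_i, y = .data$label_j,
                                    fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Functional connectivity,",
                                attr(object, "subject_id"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
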