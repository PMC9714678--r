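#' Construct a thresholded network directly
#'
#' Low-level constructor used by [threshold_by_sparsity()] and handy for
#' canonical test graphs. Edge distances downstream are `1 - w`, so a
#' binary graph with unit edge distances corresponds to `weights = 0` on
#' the adjacency support.
#'
#' @param adjacency N x N symmetric 0/1 (or logical) matrix, zero diagonal.
#' @param weights Optional N x N numeric matrix of edge weights on the
#'   adjacency support (default all zero, i.e. unit distances). Values are
#'   capped at `1 - weight_cap_eps` so edge distances stay strictly
#'   positive.
#' @param labels Optional node labels.
#' @param sparsity Fraction of possible edges retained (filled in by
#'   [threshold_by_sparsity()]).
#' @param weight_cap_eps Cap distance from 1 (default `1e-6`).
#' @return An object of class `thresholded_network`: list with `adjacency`
#'   (0/1 matrix), `weights`, `degree`, `n_nodes`, `n_edges`, `sparsity`,
#'   `labels`.
#' @export
thresholded_network <- function(adjacency, weights = NULL, labels = NULL,
                                sparsity = NA_real_, weight_cap_eps = 1e-6) {
  a <- (unclass(adjacency) != 0) * 1
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (max(abs(a - t(a))) != 0) stop("adjacency must be symmetric", call. = FALSE)
  diag(a) <- 0
  n <- nrow(a)
  if (is.null(weights)) weights <- matrix(0, n, n)
  w <- unclass(weights)
  stopifnot(is.matrix(w), all(dim(w) == n))
  w <- pmin(w, 1 - weight_cap_eps)
  w <- w * a
  w <- (w + t(w)) / 2
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- as.character(seq_len(n))
  }
  structure(
    list(adjacency = a, weights = w, degree = as.integer(rowSums(a)),
         n_nodes = n, n_edges = sum(a) / 2, sparsity = sparsity,
         labels = labels),
    class = "thresholded_network"
  )
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf("<thresholded_network> %d nodes, %d edges (sparsity %s)\n",
              x$n_nodes, x$n_edges,
              if (is.na(x$sparsity)) "NA" else format(x$sparsity)))
  invisible(x)
}

#' Proportional (sparsity) thresholding of a connectivity matrix
#'
#' Retains the `round(s * N(N-1)/2)` strongest edges of the weighted
#' matrix, after applying the negative-weight policy. Sparsity is the
#' fraction of possible edges kept; sweeping it (conventionally 0.10-0.50)
#' makes group comparisons independent of overall correlation level. Ties
#' are broken deterministically by (weight descending, row, column).
#'
#' Negative correlations have no standard interpretation under the
#' `1 - w` distance transform (distances would exceed 1), so the default
#' policy zeroes them before ranking; `"absolute"` ranks and retains
#' `|w|`, `"keep"` retains signed values and errors if a negative edge
#' would be kept.
#'
#' @param fc An `fc_matrix` (or plain symmetric matrix).
#' @param sparsity Fraction of the `N(N-1)/2` possible edges to keep, in
#'   (0, 1].
#' @param negative_weights One of `"zero"`, `"absolute"`, `"keep"`.
#' @param weight_cap_eps Retained weights are capped at
#'   `1 - weight_cap_eps` so the distance transform stays positive.
#' @return A [thresholded_network()]. If fewer positive-weight edges exist
#'   than requested, all available ones are kept with a warning (the
#'   network may be disconnected).
#' @examples
#' set.seed(1)
#' fc <- compute_fc(matrix(rnorm(240), 20, 12))
#' net <- threshold_by_sparsity(fc, 0.5)
#' net$n_edges  # round(0.5 * 66) = 33
#' @export
threshold_by_sparsity <- function(fc, sparsity,
                                  negative_weights = c("zero", "absolute", "keep"),
                                  weight_cap_eps = 1e-6) {
  negative_weights <- match.arg(negative_weights)
  w <- unclass(fc)
  stopifnot(is.matrix(w), nrow(w) == ncol(w), sparsity > 0, sparsity <= 1)
  n <- nrow(w)
  diag(w) <- 0
  rank_w <- switch(negative_weights,
                   zero = pmax(w, 0),
                   absolute = abs(w),
                   keep = w)
  m_possible <- n * (n - 1) / 2
  m_requested <- floor(sparsity * m_possible + 0.5)  # conventional half-up
  idx <- which(upper.tri(w), arr.ind = TRUE)
  vals <- rank_w[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  available <- if (negative_weights == "keep") ord else ord[vals[ord] > 0]
  m_kept <- min(m_requested, length(available))
  if (m_kept < m_requested) {
    warning("requested ", m_requested, " edges but only ", m_kept,
            " with positive weight are available; network may be disconnected",
            call. = FALSE)
  }
  keep <- available[seq_len(m_kept)]
  a <- matrix(0, n, n)
  a[idx[keep, , drop = FALSE]] <- 1
  a <- a + t(a)
  if (negative_weights == "keep" && any(rank_w[idx[keep, , drop = FALSE]] < 0)) {
    stop("negative weights retained under policy 'keep'; the 1 - w distance ",
         "transform is not defined for them", call. = FALSE)
  }
  retained <- rank_w * ((a > 0) * 1)
  labels <- rownames(w)
  thresholded_network(a, retained, labels = labels, sparsity = sparsity,
                      weight_cap_eps = weight_cap_eps)
}
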