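#' Write a cohort to disk as tab-separated files plus a JSON manifest
#'
#' One time-series TSV (header = ROI labels) and one motion TSV (columns
#' `tx_mm` ... `rz_deg`) per subject, plus `manifest.json` mapping each
#' subject to its group, files, and ground-truth correlation matrix.
#' Existing subject files are never silently overwritten.
#'
#' @param cohort A `dmn_cohort` tibble from [generate_cohort()] (or
#'   [read_cohort()]).
#' @param directory Output directory; created if missing.
#' @return The manifest path, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[k]
    ts_file <- paste0(id, "_timeseries.tsv")
    mo_file <- paste0(id, "_motion.tsv")
    for (f in c(ts_file, mo_file)) {
      if (file.exists(file.path(directory, f))) {
        stop("refusing to overwrite existing file: ", file.path(directory, f),
             call. = FALSE)
      }
    }
    write_tsv_matrix(cohort$timeseries[[k]], file.path(directory, ts_file))
    write_tsv_matrix(cohort$motion[[k]], file.path(directory, mo_file))
    entries[[k]] <- list(
      subject_id = id, group = cohort$group[k],
      timeseries = ts_file, motion = mo_file,
      has_excursion = cohort$has_excursion[k],
      ground_truth_r = cohort$ground_truth_r[[k]]
    )
  }
  cfg <- attr(cohort, "config")
  manifest <- list(
    roi_labels = colnames(cohort$timeseries[[1]]),
    tr_seconds = if (!is.null(cfg)) cfg$tr_seconds else NA_real_,
    subjects = entries
  )
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing per-subject TSVs and
#'   `manifest.json`.
#' @return A `dmn_cohort` tibble; numerically identical to the written one.
#' @export
read_cohort <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", directory, call. = FALSE)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyMatrix = TRUE)
  subs <- manifest$subjects
  rows <- vector("list", length(subs$subject_id))
  for (k in seq_along(subs$subject_id)) {
    ts <- read_timeseries_tsv(file.path(directory, subs$timeseries[k]))
    mo <- read_motion_tsv(file.path(directory, subs$motion[k]))
    gt <- subs$ground_truth_r[[k]]
    rows[[k]] <- tibble::tibble(
      subject_id = subs$subject_id[k], group = subs$group[k],
      timeseries = list(ts), motion = list(mo),
      has_excursion = subs$has_excursion[k],
      ground_truth_r = list(if (is.matrix(gt)) gt else do.call(rbind, gt))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dmn_cohort", class(out))
  out
}

#' Read a ROI time-series TSV (T rows x N ROI columns, header row)
#'
#' @param path File path.
#' @return Numeric matrix with ROI labels as column names.
#' @export
read_timeseries_tsv <- function(path) {
  read_numeric_tsv(path)
}

#' Read a motion-parameter TSV (T rows x 6 columns)
#'
#' Expected columns: `tx_mm`, `ty_mm`, `tz_mm` (translations, mm) and
#' `rx_deg`, `ry_deg`, `rz_deg` (rotations, degrees).
#'
#' @param path File path.
#' @return Numeric T x 6 matrix.
#' @export
read_motion_tsv <- function(path) {
  m <- read_numeric_tsv(path)
  expected <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  if (!identical(colnames(m), expected)) {
    stop(path, ": motion table must have columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  m
}

# Strict TSV reader: rectangular, fully numeric, precise error location.
read_numeric_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2) stop(path, ": no data rows", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n_col <- length(header)
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (r in seq_along(cells)) {
    if (length(cells[[r]]) != n_col) {
      stop(path, ": line ", r + 1, " has ", length(cells[[r]]),
           " fields, expected ", n_col, call. = FALSE)
    }
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(path, ": non-numeric value at line ", (bad - 1) %/% n_col + 2,
         ", column ", (bad - 1) %% n_col + 1, call. = FALSE)
  }
  m <- matrix(vals, ncol = n_col, byrow = TRUE)
  colnames(m) <- header
  m
}

write_tsv_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a functional-connectivity matrix as labeled CSV
#'
#' @param fc An `fc_matrix` (see [compute_fc()]).
#' @param path Output CSV path (ROI labels as header and row names).
#' @return `path`, invisibly.
#' @export
write_fc_csv <- function(fc, path) {
  utils::write.csv(as.data.frame(unclass(fc)), path)
  invisible(path)
}
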