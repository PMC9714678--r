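#' The 12-node rodent default mode network atlas
#'
#' Node table for the default mode network (DMN) as delineated in the aged
#' rat brain: six bilateral regions (auditory, orbital, parietal association,
#' prelimbic and retrosplenial cortices, plus hippocampus), giving 12 nodes.
#' The row order defines the node index used by every downstream matrix.
#'
#' @return A tibble with columns `index`, `region` (full anatomical name),
#'   `label` (short form used as column headers and matrix dimnames),
#'   `hemisphere` (`"L"`/`"R"`), and `class` (`"cortical"` or
#'   `"subcortical"`; only the hippocampus is subcortical).
#' @examples
#' dmn_rois()
#' @export
dmn_rois <- function() {
  regions <- c(
    "Auditory cortex", "Hippocampus", "Orbital cortex",
    "Parietal association cortex", "Prelimbic cortex", "Retrosplenial cortex"
  )
  short <- c("AC", "Hip", "OC", "PAC", "PrC", "RSC")
  tibble::tibble(
    index = 1:12,
    region = rep(regions, each = 2),
    hemisphere = rep(c("L", "R"), times = 6),
    label = paste0(rep(c("L", "R"), times = 6), "_", rep(short, each = 2)),
    class = ifelse(rep(short, each = 2) == "Hip", "subcortical", "cortical")
  )
}

#' @keywords internal
default_roi_labels <- function(n_rois) {
  if (n_rois == 12L) dmn_rois()$label else sprintf("ROI_%02d", seq_len(n_rois))
}
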