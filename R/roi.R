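#' Per-subject mean power over a region of interest
#'
#' Averages a tidy power map over a fixed set of channels, yielding one
#' scalar per subject (and per stage/cycle/band group present in the map) —
#' the endpoint used by the mixed ANOVAs and the clinical correlations.
#'
#' @param map Tidy power map with columns `subject`, `channel`, `value`
#'   (optionally `stage`, `cycle`, `band`).
#' @param channel_set Character vector of ROI channel labels (non-empty,
#'   all present in the map).
#' @return Tibble with the grouping columns and `value` = ROI mean.
#' @export
roi_mean <- function(map, channel_set) {
  if (length(channel_set) == 0) stop("empty ROI")
  missing <- setdiff(channel_set, unique(map$channel))
  if (length(missing)) {
    stop("ROI channels absent from map: ", paste(missing, collapse = ", "))
  }
  d <- dplyr::filter(map, channel %in% channel_set)
  grp <- dplyr::group_by(d, dplyr::across(dplyr::any_of(
    c("subject", "stage", "cycle", "band"))))
  dplyr::ungroup(dplyr::summarise(grp, value = mean(value), .groups = "drop"))
}
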