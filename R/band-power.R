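#' Canonical sleep EEG frequency bands
#'
#' The six classical bands used for topographic analysis: SWA/delta 1-4 Hz,
#' theta 4-8, alpha 8-12, sigma 12-16, beta 16-25, low gamma 25-40. All
#' intervals are half-open `[lo, hi)` so shared edges are never counted
#' twice. Optionally appends the slow/fast SWA split (0.5-2.5 / 2.5-4 Hz).
#'
#' @param swa_split Add `swa_slow` and `swa_fast` rows.
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
canonical_bands <- function(swa_split = FALSE) {
  b <- tibble::tibble(
    band = c("swa", "theta", "alpha", "sigma", "beta", "gamma"),
    lo = c(1, 4, 8, 12, 16, 25),
    hi = c(4, 8, 12, 16, 25, 40)
  )
  if (swa_split) {
    b <- dplyr::bind_rows(
      b, tibble::tibble(band = c("swa_slow", "swa_fast"),
                        lo = c(0.5, 2.5), hi = c(2.5, 4)))
  }
  b
}

#' Band power maps from a PSD
#'
#' For every band, the mean power spectral density over the bins whose
#' centre lies in the half-open interval `[lo, hi)` (mean density, µV²/Hz —
#' robust to band width). Errors when a band lies outside the PSD support.
#'
#' @param psd A `psd` object.
#' @param bands Tibble with columns `band`, `lo`, `hi` (default
#'   [canonical_bands()]).
#' @param cycle Optional cycle index stamped on the output rows.
#' @return A tidy band power map: tibble with columns `subject`, `stage`,
#'   `cycle`, `channel`, `band`, `value`, `normalization` (= "absolute").
#' @export
band_power <- function(psd, bands = canonical_bands(), cycle = NA_integer_) {
  stopifnot(all(c("band", "lo", "hi") %in% names(bands)))
  rows <- purrr::pmap(bands, function(band, lo, hi) {
    sel <- psd$freq >= lo & psd$freq < hi
    if (!any(sel)) {
      stop("band ", band, " [", lo, ", ", hi, ") has no PSD bins in support [",
           min(psd$freq), ", ", max(psd$freq), "]")
    }
    tibble::tibble(
      subject = psd$subject_id, stage = psd$stage, cycle = cycle,
      channel = rownames(psd$power), band = band,
      value = unname(rowMeans(psd$power[, sel, drop = FALSE])),
      normalization = "absolute"
    )
  })
  dplyr::bind_rows(rows)
}

#' One-hertz-bin power maps
#'
#' Band power on the 1-Hz grid: bins centred on integer frequencies with
#' bounds `[f - 0.5, f + 0.5)`, the resolution used for fine-grained
#' topographic comparison.
#'
#' @param psd A `psd` object.
#' @param bins Integer bin centres (Hz).
#' @inheritParams band_power
#' @return A tidy band power map whose `band` column holds the bin centre
#'   as character.
#' @export
one_hz_bins <- function(psd, bins = 1:40, cycle = NA_integer_) {
  bands <- tibble::tibble(band = as.character(bins),
                          lo = bins - 0.5, hi = bins + 0.5)
  bands <- bands[bands$lo < max(psd$freq) & bands$hi > min(psd$freq), ]
  band_power(psd, bands, cycle = cycle)
}

#' z-score power maps across channels
#'
#' Per subject, stage, cycle and band: standardize the channel values to
#' mean 0 and SD 1 across channels, removing global between-subject power
#' differences. Idempotent, and invariant to adding or (positively) scaling
#' a channel-common constant.
#'
#' @param map A tidy band power map (from [band_power()] or bound rows of
#'   several).
#' @return The map with `value` standardized and `normalization = "zscore"`.
#' @export
zscore_channels <- function(map) {
  grp <- dplyr::group_by(map, dplyr::across(dplyr::any_of(
    c("subject", "stage", "cycle", "band", "freq"))))
  bad <- dplyr::filter(dplyr::summarise(grp, sd = stats::sd(value),
                                        .groups = "drop"), sd == 0 | is.na(sd))
  if (nrow(bad) > 0) {
    stop("zero channel variance for subject ", bad$subject[1],
         ", band ", bad$band[1], ": z-score undefined")
  }
  out <- dplyr::ungroup(dplyr::mutate(
    grp, value = (value - mean(value)) / stats::sd(value)))
  out$normalization <- "zscore"
  out
}
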