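#' Segment a hypnogram into sleep cycles
#'
#' Conventional NREM-period/REM-period segmentation: a cycle is an NREM
#' period of at least `min_nrem_min` minutes followed by a REM period (any
#' duration for the first cycle, at least `min_rem_min` minutes thereafter;
#' shorter REM runs are absorbed into the ongoing NREM period). Wake within
#' sleep is absorbed into the current period. A final NREM period of
#' sufficient duration without subsequent REM is retained as an incomplete
#' cycle. Deterministic; a hypnogram without sleep yields an empty table.
#'
#' @param hypnogram A [hypnogram()].
#' @param min_nrem_min Minimum NREM-period duration (minutes).
#' @param min_rem_min Minimum REM-period duration after cycle 1 (minutes).
#' @return A `sleep_cycles` tibble: `cycle`, `nrem_start`, `nrem_end`,
#'   `rem_start`, `rem_end` (epoch indices; REM columns `NA` for an
#'   incomplete final cycle).
#' @export
detect_sleep_cycles <- function(hypnogram, min_nrem_min = 15,
                                min_rem_min = 5) {
  ep_min <- 60 / epoch_length_s(hypnogram)          # epochs per minute
  st <- hypnogram$stage
  onset <- which(st != "W")[1]
  empty <- tibble::tibble(cycle = integer(), nrem_start = integer(),
                          nrem_end = integer(), rem_start = integer(),
                          rem_end = integer())
  if (is.na(onset)) return(empty)

  is_nrem <- st %in% c("N1", "N2", "N3")
  is_rem <- st == "R"
  rows <- list()
  cyc_start <- onset
  nrem_count <- 0
  i <- onset
  n <- length(st)
  while (i <= n) {
    if (is_rem[i]) {
      # measure the REM run
      j <- i
      while (j < n && is_rem[j + 1]) j <- j + 1
      rem_len <- j - i + 1
      closes <- nrem_count >= min_nrem_min * ep_min &&
        (length(rows) == 0 || rem_len >= min_rem_min * ep_min)
      if (closes) {
        rows[[length(rows) + 1]] <- c(cyc_start, i - 1, i, j)
        cyc_start <- j + 1
        nrem_count <- 0
      }
      i <- j + 1
    } else {
      if (is_nrem[i]) nrem_count <- nrem_count + 1
      i <- i + 1
    }
  }
  if (nrem_count >= min_nrem_min * ep_min) {
    rows[[length(rows) + 1]] <- c(cyc_start, n, NA, NA)
  }
  if (length(rows) == 0) return(empty)
  m <- do.call(rbind, rows)
  tibble::tibble(cycle = seq_len(nrow(m)), nrem_start = m[, 1],
                 nrem_end = m[, 2], rem_start = m[, 3], rem_end = m[, 4])
}

#' Band power maps per sleep cycle
#'
#' Restricts power mapping to the scoring epochs of the requested stage
#' inside each detected cycle's NREM period and computes [band_power()] per
#' cycle. Cycles in which the subject lacks the stage entirely are reported
#' in the `missing` attribute (and omitted from the maps), mirroring the
#' listwise-deletion convention of the cycle ANOVA.
#'
#' @param recording A conditioned `eeg_recording`.
#' @param hypnogram A [hypnogram()].
#' @param cycles A `sleep_cycles` table from [detect_sleep_cycles()].
#' @param stage Stage to analyse within each cycle (default `"N3"`).
#' @param bands Band definition tibble.
#' @param bad_mask Optional sample-resolution bad mask.
#' @return A tidy band power map with a `cycle` column; attribute
#'   `missing_cycles` lists cycles without the stage.
#' @export
per_cycle_power <- function(recording, hypnogram, cycles, stage = "N3",
                            bands = canonical_bands(), bad_mask = NULL) {
  maps <- list()
  missing <- integer()
  for (k in seq_len(nrow(cycles))) {
    h2 <- hypnogram
    inside <- h2$epoch >= cycles$nrem_start[k] & h2$epoch <= cycles$nrem_end[k]
    h2$bad <- h2$bad | !inside
    es <- extract_stage_epochs(recording, h2, stage, bad_mask)
    if (n_epochs(es) == 0) {
      missing <- c(missing, k)
      next
    }
    maps[[length(maps) + 1]] <- band_power(welch_psd(es), bands,
                                           cycle = cycles$cycle[k])
  }
  out <- if (length(maps)) dplyr::bind_rows(maps) else {
    tibble::tibble(subject = character(), stage = character(),
                   cycle = integer(), channel = character(),
                   band = character(), value = numeric(),
                   normalization = character())
  }
  attr(out, "missing_cycles") <- missing
  out
}
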