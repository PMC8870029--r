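#' Extract artifact-free 6-s analysis epochs for a sleep stage
#'
#' Every retained 30-s scoring epoch of the requested stage is subdivided
#' into five non-overlapping 6-s analysis epochs aligned to the scoring
#' grid. A 6-s epoch is dropped when its source 30-s epoch carries the bad
#' flag or when it intersects the sample-resolution bad mask. Provenance
#' (source scoring epoch and slot) is recorded for every retained epoch.
#'
#' @param recording A conditioned `eeg_recording`.
#' @param hypnogram A [hypnogram()] covering (a prefix of) the recording.
#' @param stage Stage label(s) to extract: one of `"W"`, `"N1"`, `"N2"`,
#'   `"N3"`, `"R"`, or `"NREM"` (= N2 + N3).
#' @param bad_mask Optional logical vector, one element per sample.
#' @return An `epoch_set`: list with `data` (epochs x channels x samples
#'   array), `sampling_rate`, `montage`, `stage`, `subject_id`, and a
#'   `provenance` tibble. An absent stage yields an empty epoch set, not an
#'   error.
#' @export
extract_stage_epochs <- function(recording, hypnogram, stage,
                                 bad_mask = NULL) {
  stages <- if (identical(stage, "NREM")) c("N2", "N3") else stage
  fs <- recording$sampling_rate
  ep_len <- epoch_length_s(hypnogram)
  sub_s <- 6
  n_sub <- ep_len / sub_s
  ns_sub <- sub_s * fs
  ntotal <- ncol(recording$data)
  sel <- which(hypnogram$stage %in% stages & !hypnogram$bad)
  rows <- list()
  for (e in sel) {
    start0 <- (e - 1) * ep_len * fs
    for (k in seq_len(n_sub)) {
      i0 <- start0 + (k - 1) * ns_sub
      if (i0 + ns_sub > ntotal) next
      idx <- (i0 + 1):(i0 + ns_sub)
      if (!is.null(bad_mask) && any(bad_mask[idx])) next
      rows[[length(rows) + 1]] <- c(e, k, i0 + 1)
    }
  }
  prov <- if (length(rows)) {
    m <- do.call(rbind, rows)
    tibble::tibble(source_epoch = m[, 1], slot = m[, 2], start_sample = m[, 3])
  } else {
    tibble::tibble(source_epoch = integer(), slot = integer(),
                   start_sample = integer())
  }
  data <- array(0, dim = c(nrow(prov), nrow(recording$data), ns_sub))
  for (i in seq_len(nrow(prov))) {
    idx <- prov$start_sample[i]:(prov$start_sample[i] + ns_sub - 1)
    data[i, , ] <- recording$data[, idx]
  }
  structure(
    list(data = data, sampling_rate = fs, montage = recording$montage,
         stage = paste(stage, collapse = "+"),
         subject_id = recording$subject_id, provenance = prov),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set (", x$stage, "): ", dim(x$data)[1], " six-second epochs x ",
      dim(x$data)[2], " channels @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

n_epochs <- function(epoch_set) dim(epoch_set$data)[1]

#' Select clean pre-sleep wakefulness
#'
#' Harvests wake epochs in the window from `window_min[2]` to
#' `window_min[1]` minutes before sleep onset (the first non-wake scoring
#' epoch), artifact-filtered like any other stage. Subjects retaining less
#' than `min_clean_minutes` of clean wake are flagged as excluded from the
#' wake analysis; their sleep analyses are unaffected.
#'
#' @inheritParams extract_stage_epochs
#' @param min_clean_minutes Minimum clean wake duration to keep the subject.
#' @param window_min `c(near, far)` window bounds in minutes before onset.
#' @return A list with `epochs` (an `epoch_set`), `excluded` (logical),
#'   `clean_minutes`, and `onset_epoch`.
#' @export
select_presleep_wake <- function(recording, hypnogram, bad_mask = NULL,
                                 min_clean_minutes = 5,
                                 window_min = c(10, 50)) {
  ep_len <- epoch_length_s(hypnogram)
  onset <- which(hypnogram$stage != "W")[1]
  if (is.na(onset)) onset <- nrow(hypnogram) + 1
  far <- onset - window_min[2] * 60 / ep_len
  near <- onset - window_min[1] * 60 / ep_len
  keep <- hypnogram$epoch >= far & hypnogram$epoch < near
  h2 <- hypnogram
  h2$bad <- hypnogram$bad | !keep            # restrict extraction to window
  es <- extract_stage_epochs(recording, h2, "W", bad_mask)
  es$stage <- "wake_presleep"
  clean_min <- n_epochs(es) * 6 / 60
  list(epochs = es, excluded = clean_min < min_clean_minutes,
       clean_minutes = clean_min, onset_epoch = onset)
}
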