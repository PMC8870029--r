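#' Mark bad data segments by a majority-channel amplitude rule
#'
#' Automatic surrogate for visual artifact scoring: a sample is marked bad
#' when more than half of the channels exceed the amplitude threshold
#' somewhere within a sliding 1-s window around it. Good gaps shorter than
#' `min_good_gap_s` between bad intervals are absorbed into the mask, so
#' tiny clean islands inside an artifact are not kept.
#'
#' @param recording An `eeg_recording`.
#' @param amplitude_threshold_uv Absolute amplitude threshold in µV.
#' @param min_good_gap_s Minimum clean gap (s) allowed to separate two bad
#'   intervals.
#' @param majority Fraction of channels that must exceed the threshold.
#' @return Logical vector, one element per sample (`TRUE` = bad).
#' @export
mark_bad_segments <- function(recording, amplitude_threshold_uv = 500,
                              min_good_gap_s = 1, majority = 0.5) {
  if (amplitude_threshold_uv <= 0) stop("threshold must be positive")
  fs <- recording$sampling_rate
  x <- recording$data
  n <- ncol(x)
  w <- max(1, round(fs))                       # 1-s window
  exceed <- abs(x) > amplitude_threshold_uv
  # per channel: does any sample in the centred window exceed?
  frac <- rep(0, n)
  half <- floor(w / 2)
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  for (ch in seq_len(nrow(x))) {
    cs <- cumsum(c(0, exceed[ch, ]))
    frac <- frac + as.numeric((cs[hi + 1] - cs[lo + 1]) > 0)
  }
  bad <- frac / nrow(x) > majority
  close_short_gaps(bad, round(min_good_gap_s * fs))
}

# absorb good runs shorter than min_gap samples between two bad runs
close_short_gaps <- function(bad, min_gap) {
  r <- rle(bad)
  if (length(r$lengths) >= 3) {
    inner <- 2:(length(r$lengths) - 1)
    fill <- !r$values[inner] & r$lengths[inner] < min_gap
    r$values[inner][fill] <- TRUE
  }
  inverse.rle(r)
}

#' Detect bad channels by neighbourhood power deviation
#'
#' Automatic surrogate for visual channel rejection: a channel is flagged
#' when its log total signal power deviates from the median log power of its
#' montage neighbours by more than `psd_deviation_z` robust z-units (median
#' and MAD of the deviations across channels). Flat and grossly noisy
#' channels stand out sharply; a channel duplicating a good neighbour has
#' zero deviation and is never flagged.
#'
#' @param recording An `eeg_recording`.
#' @param psd_deviation_z Robust z threshold.
#' @param graph Optional `adjacency_graph`; computed from the montage when
#'   missing.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(recording, psd_deviation_z = 5,
                                graph = NULL) {
  if (is.null(graph)) graph <- electrode_adjacency(recording$montage)
  x <- recording$data
  logp <- log(rowMeans(x^2) + 1e-12)
  names(logp) <- rownames(x)
  dev <- vapply(graph$labels, function(lab) {
    nb <- graph$neighbours[[lab]]
    logp[[lab]] - stats::median(logp[nb])
  }, numeric(1))
  s <- stats::mad(dev)
  if (s < 1e-12) s <- max(stats::sd(dev), 1e-12)
  z <- (dev - stats::median(dev)) / s
  graph$labels[abs(z) > psd_deviation_z]
}
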