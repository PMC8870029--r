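#' Welch power spectral density of an epoch set
#'
#' Welch's averaged modified periodogram per channel: every 6-s analysis
#' epoch is cut into 8 Hamming-windowed segments with 50% overlap (segment
#' length = epoch length / 4.5, i.e. 1.33 s, giving a frequency resolution
#' of about 0.75 Hz), periodograms are averaged within the epoch and then
#' across epochs. Density scaling (µV²/Hz, one-sided); bins are restricted
#' to the 0.5-45 Hz support of the conditioned signal.
#'
#' @param epoch_set An `epoch_set` from [extract_stage_epochs()].
#' @param n_segments Segments per epoch.
#' @param freq_range Retained frequency support in Hz.
#' @return A `psd` object: list with `power` (channels x bins matrix),
#'   `freq` (bin centres, Hz), `bin_width`, `n_epochs`, `stage`,
#'   `subject_id`, `montage`.
#' @export
welch_psd <- function(epoch_set, n_segments = 8, freq_range = c(0.5, 45)) {
  if (n_epochs(epoch_set) == 0) {
    stop("no data for stage ", epoch_set$stage)
  }
  fs <- epoch_set$sampling_rate
  d <- epoch_set$data
  ne <- dim(d)[1]
  nch <- dim(d)[2]
  ns <- dim(d)[3]
  seg <- floor(ns / ((n_segments + 1) / 2))     # 50% overlap coverage
  starts <- round(seq(0, ns - seg, length.out = n_segments))
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))
  u <- sum(win^2)
  freq <- (seq_len(seg) - 1) * fs / seg
  keep <- freq >= freq_range[1] & freq <= min(freq_range[2], fs / 2)

  acc <- matrix(0, nch, sum(keep))
  for (ch in seq_len(nch)) {
    segs <- matrix(0, seg, ne * n_segments)
    col <- 1
    for (e in seq_len(ne)) {
      for (s in starts) {
        segs[, col] <- d[e, ch, (s + 1):(s + seg)] * win
        col <- col + 1
      }
    }
    pxx <- Mod(stats::mvfft(segs))^2 / (fs * u)
    pxx <- rowMeans(pxx) * 2                    # one-sided
    acc[ch, ] <- pxx[keep]
  }
  rownames(acc) <- epoch_set$montage$channel
  structure(
    list(power = acc, freq = freq[keep], bin_width = fs / seg,
         n_epochs = ne, stage = epoch_set$stage,
         subject_id = epoch_set$subject_id, montage = epoch_set$montage),
    class = "psd"
  )
}

#' @export
print.psd <- function(x, ...) {
  cat("Welch PSD (", x$stage, "): ", nrow(x$power), " channels x ",
      length(x$freq), " bins (", round(min(x$freq), 2), "-",
      round(max(x$freq), 2), " Hz, width ", round(x$bin_width, 3),
      " Hz), ", x$n_epochs, " epochs\n", sep = "")
  invisible(x)
}

#' Tidy a PSD into a tibble
#' @param x A `psd`.
#' @param ... Unused.
#' @return Tibble with `subject`, `stage`, `channel`, `freq`, `power`.
#' @method tidy psd
#' @export
tidy.psd <- function(x, ...) {
  tibble::tibble(
    subject = x$subject_id, stage = x$stage,
    channel = rep(rownames(x$power), times = length(x$freq)),
    freq = rep(x$freq, each = nrow(x$power)),
    power = as.vector(x$power)
  )
}

#' Channel-averaged spectrum of a PSD
#'
#' Mean PSD over all scalp channels, the quantity compared between groups in
#' whole-scalp spectrum tests.
#'
#' @param psd A `psd`.
#' @return Tibble with `subject`, `freq`, `value`.
#' @export
channel_average_spectrum <- function(psd) {
  tibble::tibble(subject = psd$subject_id, freq = psd$freq,
                 value = colMeans(psd$power))
}
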