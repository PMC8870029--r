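#' Multichannel EEG recording object
#'
#' Thin matrix-backed container for a continuous recording: a channels x
#' samples matrix in microvolts, the sampling rate, the montage, and the
#' reference scheme. Row order matches the montage channel order.
#'
#' @param data Numeric matrix, channels x samples (µV). Row names, if
#'   present, must equal the montage labels.
#' @param sampling_rate Sampling rate in Hz.
#' @param montage An `eeg_montage` with one row per data row.
#' @param subject_id Subject identifier string.
#' @param reference Reference scheme: `"vertex"`, `"average"` or `"other"`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, sampling_rate, montage,
                          subject_id = "S000",
                          reference = c("vertex", "average", "other")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  validate_montage(montage)
  if (nrow(data) != nrow(montage)) {
    stop("data has ", nrow(data), " rows but montage has ", nrow(montage),
         " channels")
  }
  if (anyNA(data)) stop("recording contains NA samples")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  rownames(data) <- montage$channel
  structure(
    list(data = data, sampling_rate = sampling_rate, montage = montage,
         subject_id = subject_id, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording", x$subject_id, ":", nrow(x$data), "channels x",
      ncol(x$data), "samples @", x$sampling_rate, "Hz (",
      round(ncol(x$data) / x$sampling_rate / 60, 1), "min ),",
      x$reference, "reference\n")
  invisible(x)
}

n_samples <- function(recording) ncol(recording$data)

recording_duration <- function(recording) {
  ncol(recording$data) / recording$sampling_rate
}
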