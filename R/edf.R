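# Minimal EDF (European Data Format) writer/reader: 16-bit integer samples,
# fixed physical range +-1000 uV, 1-s data records. Covers exactly the
# subset of the format the fixture files use; no annotations, no
# discontinuous records.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to 16-bit integers over a fixed physical range of
#' +-1000 µV (values outside are clipped) and stored in 1-s data records;
#' a trailing partial second is dropped. The sampling rate must be an
#' integer.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @param phys_range Physical range in µV mapped onto the 16-bit digital
#'   range.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, phys_range = c(-1000, 1000)) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- recording$data
  nch <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  labels <- rownames(x)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, eos = NULL)
  wr("0", 8)
  wr(paste("X X X X", recording$subject_id), 80)
  wr(paste("Startdate 01-JAN-2000 X X X synthetic"), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 + 256 * nch, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(nch, 4)
  for (lab in labels) wr(paste("EEG", lab), 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(phys_range[1], 8)
  for (i in seq_len(nch)) wr(phys_range[2], 8)
  for (i in seq_len(nch)) wr(-32767, 8)
  for (i in seq_len(nch)) wr(32767, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(fs, 8)
  for (i in seq_len(nch)) wr("", 32)

  scale <- 65534 / diff(phys_range)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- x[, idx, drop = FALSE]
    dig <- round((pmin(pmax(block, phys_range[1]), phys_range[2]) -
                    mean(phys_range)) * scale)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the header and 16-bit data records back into an `eeg_recording`.
#' If no montage is supplied and the channel labels match the deterministic
#' [make_montage()] layout for that channel count, that montage is
#' attached.
#'
#' @param path EDF file path.
#' @param montage Optional `eeg_montage` matching the stored channels.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur

  x <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = nch * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = nch)
    x[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  x <- x * gain + (phys_max + phys_min) / 2
  if (is.null(montage)) {
    if (nch >= 8 && nch <= 256) {
      cand <- make_montage(nch)
      if (identical(cand$channel, unname(labels))) montage <- cand
    }
    if (is.null(montage)) {
      stop("supply a montage: stored labels do not match a deterministic layout")
    }
  }
  subject <- sub("^X X X X ", "", patient)
  eeg_recording(x, fs, montage, subject_id = subject, reference = "vertex")
}
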