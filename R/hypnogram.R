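#' Hypnogram container
#'
#' Per-30-s-epoch sleep stage labels with a bad-segment flag, as produced by
#' standard sleep scoring. Stages follow the usual vocabulary: W (wake),
#' N1/N2/N3 (NREM depth), R (REM).
#'
#' @param stages Character vector over \{W, N1, N2, N3, R\}.
#' @param bad Logical vector (same length): epoch contains unusable data.
#' @param epoch_length_s Scoring epoch length, fixed at 30 s.
#' @return A `hypnogram`: tibble with columns `epoch`, `stage`, `bad`.
#' @export
hypnogram <- function(stages, bad = rep(FALSE, length(stages)),
                      epoch_length_s = 30) {
  stages <- as.character(stages)
  if (!all(stages %in% c("W", "N1", "N2", "N3", "R"))) {
    stop("stages must be in {W, N1, N2, N3, R}")
  }
  if (length(bad) != length(stages)) stop("stages and bad must match in length")
  out <- tibble::tibble(epoch = seq_along(stages), stage = stages,
                        bad = as.logical(bad))
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("hypnogram", class(out))
  out
}

epoch_length_s <- function(h) attr(h, "epoch_length_s") %||% 30

#' Simulate a night's hypnogram
#'
#' Builds a plausible stage sequence: an initial wake block (at least 10
#' minutes), then `n_cycles` sleep cycles each consisting of an NREM block of
#' at least 15 minutes (N1 then N2 then N3, with N3 shrinking over
#' successive cycles but always present) followed by a REM block of at least
#' 5 minutes. Block lengths are drawn reproducibly from the seed; the same
#' `(n_cycles, seed)` always gives the identical label sequence.
#'
#' @param n_cycles Number of sleep cycles (>= 1).
#' @param seed Integer seed.
#' @param wake_minutes Approximate pre-sleep wake duration (>= 10).
#' @param nrem_minutes Approximate NREM-period duration per cycle (>= 16).
#' @param rem_minutes Approximate REM-period duration per cycle (>= 5).
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(n_cycles, seed = 1, wake_minutes = 12,
                               nrem_minutes = 18, rem_minutes = 6) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  wake_minutes <- max(10, wake_minutes)
  nrem_minutes <- max(16, nrem_minutes)
  rem_minutes <- max(5, rem_minutes)
  withr::with_seed(seed, {
    ep <- function(min) round(min * 2)           # minutes -> 30-s epochs
    stages <- rep("W", ep(wake_minutes) + sample(0:4, 1))
    for (k in seq_len(n_cycles)) {
      n1 <- ep(1) + sample(0:2, 1)
      n3 <- max(ep(4), ep(nrem_minutes - 8 - 2 * (k - 1)) + sample(-2:2, 1))
      n2 <- ep(nrem_minutes) - ep(1) - n3 - ep(2) + sample(0:6, 1)
      n2 <- max(n2, ep(3))
      n2b <- ep(2) + sample(0:2, 1)
      rem <- max(ep(5), ep(rem_minutes - 1) + sample(0:4, 1))
      stages <- c(stages, rep("N1", n1), rep("N2", n2), rep("N3", n3),
                  rep("N2", n2b), rep("R", rem))
    }
    hypnogram(stages)
  })
}

#' Read / write a hypnogram as TSV
#'
#' Plain-text interchange format with columns `epoch_index`, `stage`,
#' `bad_flag` (0/1), one row per 30-s epoch.
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @return `read_hypnogram()` returns a `hypnogram`; `write_hypnogram()`
#'   returns `path` invisibly.
#' @export
write_hypnogram <- function(h, path) {
  d <- data.frame(epoch_index = h$epoch, stage = h$stage,
                  bad_flag = as.integer(h$bad))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  hypnogram(d$stage, bad = d$bad_flag != 0)
}
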