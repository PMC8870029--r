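#' Construct a deterministic scalp montage
#'
#' Places `n_channels` sensors near-uniformly on the upper unit hemisphere
#' (head-centred coordinates: x right, y anterior, z superior) using the
#' Fibonacci spiral, and tags every channel with one scalp region
#' (frontopolar, frontal, central, temporal, parietal, occipital). The layout
#' is a deterministic function of `n_channels`: the same count always yields
#' the identical montage, labels `E001`, `E002`, ...
#'
#' @param n_channels Number of sensors, between 8 and 256.
#' @return An `eeg_montage`: a tibble with columns `channel`, `x`, `y`, `z`,
#'   `region`.
#' @examples
#' m <- make_montage(64)
#' table(m$region)
#' @export
make_montage <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 ||
      n_channels < 8 || n_channels > 256 || n_channels %% 1 != 0) {
    stop("n_channels must be a single integer in [8, 256]")
  }
  n <- as.integer(n_channels)
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n                    # vertex (z=1) down to the rim
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- i * golden
  x <- r * cos(theta)
  y <- r * sin(theta)
  az <- atan2(x, y)                         # 0 = anterior, +-pi = posterior
  region <- montage_region(az, z)
  out <- tibble::tibble(
    channel = sprintf("E%03d", i),
    x = x, y = y, z = z, region = region
  )
  class(out) <- c("eeg_montage", class(out))
  out
}

# single-assignment cascade: every (azimuth, elevation) pair falls in exactly
# one region
montage_region <- function(az, z) {
  a <- abs(az)
  dplyr::case_when(
    z > 0.75 ~ "central",
    a <= pi / 6 & z <= 0.35 ~ "frontopolar",
    a < pi / 3 ~ "frontal",
    a < 2 * pi / 3 & z <= 0.4 ~ "temporal",
    a < 2 * pi / 3 ~ "parietal",
    z <= 0.35 ~ "occipital",
    .default = "parietal"
  )
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage),
            all(c("channel", "x", "y", "z", "region") %in% names(montage)))
  if (anyDuplicated(montage$channel)) stop("montage channel labels must be unique")
  norms <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(abs(norms - 1) > 1e-9)) stop("montage positions must lie on the unit sphere")
  invisible(montage)
}

montage_positions <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  rownames(p) <- montage$channel
  p
}

#' Select a contiguous region of interest around a scalp location
#'
#' Returns the `n` channels geodesically closest to a target direction on the
#' scalp sphere; by construction the set is spatially contiguous. The default
#' target is a posterior midline location, giving a centro-posterior ROI.
#'
#' @param montage An `eeg_montage`.
#' @param n Number of channels to select.
#' @param center Unit 3-vector giving the ROI centre direction.
#' @return Character vector of channel labels.
#' @export
select_roi_channels <- function(montage, n,
                                center = c(0, -0.7, sqrt(1 - 0.49))) {
  validate_montage(montage)
  if (n < 1 || n > nrow(montage)) stop("n out of range")
  center <- center / sqrt(sum(center^2))
  pos <- montage_positions(montage)
  d <- acos(pmin(1, pmax(-1, pos %*% center)))
  montage$channel[order(d)[seq_len(n)]]
}

#' Read / write a montage as CSV
#'
#' Plain-text interchange format: columns `label,x,y,z,region`.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `read_montage()` returns an `eeg_montage`; `write_montage()`
#'   returns `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  validate_montage(montage)
  out <- data.frame(label = montage$channel, x = montage$x, y = montage$y,
                    z = montage$z, region = montage$region)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(channel = d$label, x = d$x, y = d$y, z = d$z,
                        region = d$region)
  class(out) <- c("eeg_montage", class(out))
  validate_montage(out)
  out
}
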