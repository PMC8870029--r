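#' Spherical-spline interpolation of bad channels
#'
#' Replaces the signals of the listed channels with spherical-spline
#' estimates computed from the remaining good channels (order m = 4
#' Legendre weighting, series truncated at degree 7, ridge regularization
#' 1e-5 on the spline system). Good channels are returned untouched. The
#' spline reproduces constant fields exactly up to the regularization, and
#' smooth dipolar fields to within a few percent on realistic montages.
#'
#' @param recording An `eeg_recording`.
#' @param bad_channels Character vector of channel labels to rebuild; must
#'   be fewer than a quarter of the channels.
#' @param order Legendre weighting order m.
#' @param degree Truncation degree of the Legendre series.
#' @param lambda Ridge regularization added to the spline system.
#' @return The `eeg_recording` with bad channels replaced.
#' @export
spherical_spline_interpolate <- function(recording, bad_channels,
                                         order = 4, degree = 7,
                                         lambda = 1e-5) {
  labels <- recording$montage$channel
  bad_channels <- unique(bad_channels)
  if (length(bad_channels) == 0) return(recording)
  unknown <- setdiff(bad_channels, labels)
  if (length(unknown)) stop("unknown channels: ", paste(unknown, collapse = ", "))
  if (length(bad_channels) >= length(labels) / 4) {
    stop("refusing to interpolate ", length(bad_channels), " of ",
         length(labels), " channels (more than a quarter are bad)")
  }
  pos <- montage_positions(recording$montage)
  good <- setdiff(labels, bad_channels)
  gi <- match(good, labels)
  bi <- match(bad_channels, labels)

  G <- legendre_g(tcrossprod(pos[gi, , drop = FALSE]), order, degree)
  Gb <- legendre_g(pos[bi, , drop = FALSE] %*% t(pos[gi, , drop = FALSE]),
                   order, degree)
  ng <- length(gi)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(recording$data[gi, , drop = FALSE], 0)
  coef <- solve(A, rhs)                       # (ng+1) x samples
  est <- Gb %*% coef[seq_len(ng), , drop = FALSE] +
    matrix(coef[ng + 1, ], nrow = length(bi), ncol = ncol(recording$data),
           byrow = TRUE)
  recording$data[bi, ] <- est
  recording
}

# spherical spline kernel g(cos gamma) = sum_n (2n+1) / (n(n+1))^m P_n(x) / 4pi
legendre_g <- function(x, order, degree) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  p_prev <- matrix(1, nrow(x), ncol(x))       # P_0
  p_cur <- x                                  # P_1
  g <- (2 * 1 + 1) / (1 * 2)^order * p_cur
  for (n in 2:degree) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    g <- g + (2 * n + 1) / (n * (n + 1))^order * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  g / (4 * pi)
}

#' Re-reference a recording to the channel average
#'
#' Subtracts the instantaneous mean over all channels from every channel;
#' the output channel mean is zero at every sample. Idempotent.
#'
#' @param recording An `eeg_recording`.
#' @return The average-referenced `eeg_recording`.
#' @export
average_reference <- function(recording) {
  if (nrow(recording$data) < 2) stop("need at least 2 channels")
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording$reference <- "average"
  recording
}
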