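#' First-order high-pass filter (single-pole RC)
#'
#' Causal IIR high-pass reproducing a single resistor-capacitor stage,
#' applied forward in time to every channel:
#' `y[n] = a * (y[n-1] + x[n] - x[n-1])` with `a = RC / (RC + 1/fs)` and
#' `RC = 1 / (2 pi cutoff)`. Removes the DC component asymptotically while
#' leaving the passband essentially untouched (gain at 10 Hz with the default
#' 0.1 Hz cutoff is within a fraction of a percent of unity).
#'
#' @param recording An `eeg_recording`.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @return The filtered `eeg_recording`.
#' @export
highpass_first_order <- function(recording, cutoff = 0.1) {
  fs <- recording$sampling_rate
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  rc <- 1 / (2 * pi * cutoff)
  a <- rc / (rc + 1 / fs)
  x <- recording$data
  y <- t(apply(x, 1, function(ch) {
    stats::filter(a * (ch - c(0, ch[-length(ch)])), a, method = "recursive")
  }))
  recording$data <- matrix(as.numeric(y), nrow = nrow(x),
                           dimnames = dimnames(x))
  recording
}

# analytic magnitude response of the continuous one-pole RC high-pass
rc_highpass_gain <- function(freq, cutoff) {
  w <- freq / cutoff
  w / sqrt(1 + w^2)
}

#' Zero-phase Kaiser-window FIR band-pass filter
#'
#' Linear-phase FIR band-pass designed with a Kaiser window, applied
#' forward and time-reversed so the net filter has exactly zero phase (the
#' effective magnitude response is the square of the single-pass design).
#' The design targets at least 60 dB single-pass stopband attenuation and a
#' passband ripple well under 0.1 dB; transition bands default to 0.4 Hz
#' below the low edge and 5 Hz above the high edge. Edges are zero-padded;
#' the first and last kernel-length samples carry the usual filter
#' transients.
#'
#' @param recording An `eeg_recording`.
#' @param band Passband `c(lo, hi)` in Hz, within (0, Nyquist).
#' @param transition Transition widths `c(low, high)` in Hz.
#' @param attenuation_db Single-pass stopband attenuation target.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_fir_zero_phase <- function(recording, band = c(0.5, 45),
                                    transition = c(0.4, 5),
                                    attenuation_db = 60) {
  fs <- recording$sampling_rate
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stop("band must be an increasing interval within (0, Nyquist)")
  }
  b <- design_kaiser_bandpass(band, fs, transition, attenuation_db)
  x <- recording$data
  y <- zero_phase_apply(b, x)
  recording$data <- y
  recording
}

# Kaiser FIR design: order from the Kaiser formula, beta from the
# attenuation target
design_kaiser_bandpass <- function(band, fs, transition, attenuation_db) {
  a <- attenuation_db
  beta <- if (a > 50) 0.1102 * (a - 8.7) else if (a >= 21) {
    0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
  } else 0
  dw <- 2 * pi * min(transition) / fs
  n <- ceiling((a - 7.95) / (2.285 * dw))
  n <- n + n %% 2                               # even order, odd length
  edges <- c(band[1] - transition[1] / 2, band[2] + transition[2] / 2)
  w <- pmin(pmax(edges / (fs / 2), 1e-6), 1 - 1e-6)
  signal::fir1(n, w, type = "pass",
               window = signal::kaiser(n + 1, beta), scale = TRUE)
}

# zero-phase FIR application: convolve with b * reversed(b) (an exactly
# symmetric kernel, equivalent to filtering forward then backward with
# zero-padded edges), via FFT, centred so the delay cancels
zero_phase_apply <- function(b, x) {
  L <- length(b)
  n <- ncol(x)
  nfft <- stats::nextn(n + 2 * L, 2)
  B <- stats::fft(c(b, rep(0, nfft - L)))
  H <- B * Conj(B)                              # |B|^2: zero phase
  Y <- apply(x, 1, function(ch) {
    z <- stats::fft(stats::fft(c(ch, rep(0, nfft - n))) * H, inverse = TRUE)
    Re(z[seq_len(n)]) / nfft      # |B|^2 kernel is centred at lag 0
  })
  matrix(t(Y), nrow = nrow(x), dimnames = dimnames(x))
}

# designed zero-phase magnitude response at the given frequencies
fir_designed_response <- function(b, freq, fs) {
  w <- outer(freq * 2 * pi / fs, seq_along(b) - 1)
  h <- (cos(w) %*% b) + 1i * (-sin(w) %*% b)
  as.numeric(Mod(h)^2)
}
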