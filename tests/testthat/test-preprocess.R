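# Signal conditioning: filters, artifact masking, bad channels,
# spherical-spline interpolation, average reference, epoch extraction.

test_that("first-order high-pass rejects DC and matches the analytic RC gain", {
  fs <- 120
  m <- make_montage(8)
  n <- fs * 120
  x <- matrix(100, 8, n)                      # constant input
  rec <- highpass_first_order(eeg_recording(x, fs, m), 0.1)
  # steady state below 1% of the input after 10 time constants (~16 s)
  expect_lt(max(abs(rec$data[, (fs * 20):n])), 1)

  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  xs <- matrix(rep(sin(2 * pi * 10 * tt), 8), 8, byrow = TRUE)
  hp <- highpass_first_order(eeg_recording(xs, fs, m), 0.1)
  gain <- sd(hp$data[1, 2000:12000]) / sd(xs[1, 2000:12000])
  expect_lt(abs(gain - sleeptopo:::rc_highpass_gain(10, 0.1)), 0.01)

  set.seed(1)
  xw <- matrix(rnorm(8 * n), 8)
  hw <- highpass_first_order(eeg_recording(xw, fs, m), 0.1)
  expect_lt(var(hw$data[1, ]), var(xw[1, ]))
  expect_error(highpass_first_order(eeg_recording(xw, fs, m), 70), "Nyquist")
})

test_that("zero-phase band-pass: stopband, zero lag, and designed response", {
  fs <- 250
  m <- make_montage(8)
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x60 <- matrix(rep(sin(2 * pi * 60 * tt), 8), 8, byrow = TRUE) * 50
  bp <- bandpass_fir_zero_phase(eeg_recording(x60, fs, m))
  atten <- 20 * log10(sd(bp$data[1, 4000:6000]) / sd(x60[1, 4000:6000]))
  expect_lt(atten, -40)

  # 10 Hz sine: cross-correlation peak at exactly zero lag
  x10 <- matrix(rep(sin(2 * pi * 10 * tt), 8), 8, byrow = TRUE)
  b10 <- bandpass_fir_zero_phase(eeg_recording(x10, fs, m))
  cc <- ccf(b10$data[1, 4000:8000], x10[1, 4000:8000], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # chirp: empirical magnitude within 5% of the designed zero-phase response
  f0 <- 1; f1 <- 45; dur <- 60
  tc <- seq(0, dur - 1 / fs, by = 1 / fs)
  chirp <- sin(2 * pi * (f0 * tc + (f1 - f0) / (2 * dur) * tc^2))
  xc <- matrix(rep(chirp, 8), 8, byrow = TRUE)
  bc <- bandpass_fir_zero_phase(eeg_recording(xc, fs, m))
  b <- sleeptopo:::design_kaiser_bandpass(c(0.5, 45), fs, c(0.4, 5), 60)
  spec_in <- Mod(fft(xc[1, ]))^2
  spec_out <- Mod(fft(bc$data[1, ]))^2
  freqs <- (seq_along(spec_in) - 1) * fs / length(spec_in)
  sel <- freqs >= 2 & freqs <= 40
  emp <- sqrt(spec_out[sel] / spec_in[sel])
  des <- sleeptopo:::fir_designed_response(b, freqs[sel], fs)
  expect_lt(max(abs(emp - des)), 0.05)
})

test_that("filter pipeline is order-stable on white noise", {
  fs <- 120
  m <- make_montage(8)
  set.seed(2)
  x <- matrix(rnorm(8 * fs * 60), 8)
  rec <- eeg_recording(x, fs, m)
  a <- bandpass_fir_zero_phase(highpass_first_order(rec))$data
  b <- highpass_first_order(bandpass_fir_zero_phase(rec))$data
  # past the FIR kernel length and the IIR settling time the two LTI
  # orderings agree to numerical precision
  mid <- (20 * fs):(40 * fs)
  rms <- sqrt(mean((a[, mid] - b[, mid])^2))
  expect_lt(rms, 1e-6 * sd(x))
})

test_that("bad-segment masking recovers an injected majority transient", {
  fs <- 100
  m <- make_montage(8)
  set.seed(3)
  x <- matrix(rnorm(8 * fs * 120, sd = 20), 8)
  rec <- eeg_recording(x, fs, m)
  expect_false(any(mark_bad_segments(rec, 500)))

  idx <- (fs * 50 + 1):(fs * 52)               # 2-s transient on 6/8 channels
  x2 <- x
  x2[1:6, idx] <- x2[1:6, idx] + 800
  rec2 <- eeg_recording(x2, fs, m)
  mask <- mark_bad_segments(rec2, 500)
  expect_true(all(mask[idx]))
  r <- rle(mask)
  expect_equal(sum(r$values), 1)               # exactly one bad interval
  # near-zero threshold: everything bad
  expect_true(all(mark_bad_segments(rec, 1e-9)))
})

test_that("bad channels are detected from neighbourhood power deviation", {
  fs <- 100
  m <- make_montage(32)
  set.seed(4)
  x <- matrix(rnorm(32 * fs * 60, sd = 20), 32)
  rec <- eeg_recording(x, fs, m)
  expect_length(detect_bad_channels(rec, 5), 0)

  x2 <- x
  x2[c(3, 11, 20), ] <- x2[c(3, 11, 20), ] * 0.01    # three flat channels
  found <- detect_bad_channels(eeg_recording(x2, fs, m), 5)
  expect_setequal(found, m$channel[c(3, 11, 20)])

  x3 <- x
  x3[5, ] <- x3[6, ]                                  # duplicate a good channel
  expect_length(detect_bad_channels(eeg_recording(x3, fs, m), 5), 0)
})

test_that("spherical spline reproduces constants, smooth fields, and is a no-op on none", {
  fs <- 100
  m <- make_montage(64)
  pos <- as.matrix(m[, c("x", "y", "z")])
  # constant field
  recc <- eeg_recording(matrix(7, 64, 50), fs, m)
  out <- spherical_spline_interpolate(recc, "E010")
  expect_lt(max(abs(out$data["E010", ] - 7)) / 7, 1e-3)

  # smooth dipolar field: error under 10% of the field SD
  field <- as.vector(pos %*% c(0.4, -0.3, 0.85))
  recd <- eeg_recording(matrix(field, 64, 5), fs, m)
  outd <- spherical_spline_interpolate(recd, "E025")
  expect_lt(abs(outd$data["E025", 1] - field[25]), 0.1 * sd(field))
  # good channels untouched
  expect_identical(outd$data[-25, ], recd$data[-25, ])

  expect_identical(spherical_spline_interpolate(recd, character(0)), recd)
  expect_error(spherical_spline_interpolate(recd, m$channel[1:20]), "quarter")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(5)
  m <- make_montage(8)
  rec <- eeg_recording(matrix(rnorm(8 * 100), 8), 100, m)
  ar <- average_reference(rec)
  expect_lt(max(abs(colMeans(ar$data))), 1e-10)
  expect_equal(average_reference(ar)$data, ar$data, tolerance = 1e-12)
  # two opposite channels are already zero-mean
  half <- make_montage(8)
  x2 <- rbind(rnorm(50), 0, 0, 0, 0, 0, 0, 0)
  x2[2, ] <- -x2[1, ]
  rec2 <- eeg_recording(x2[c(1, 2, 3:8), ] * c(1, 1, rep(0, 6)), 100, half)
  expect_equal(average_reference(rec2)$data[1:2, ], rec2$data[1:2, ],
               tolerance = 1e-12)
})

test_that("epoch extraction counts and filters as specified", {
  fs <- 100
  m <- make_montage(8)
  h <- hypnogram(c(rep("W", 2), rep("N3", 10), rep("R", 3)))
  n <- nrow(h) * 30 * fs
  rec <- eeg_recording(matrix(rnorm(8 * n), 8), fs, m)

  es <- extract_stage_epochs(rec, h, "N3")
  expect_equal(sleeptopo:::n_epochs(es), 50)    # 10 x 30/6

  # one N3 epoch with a bad middle 6 s loses exactly one subepoch
  mask <- rep(FALSE, n)
  e3 <- 5                                       # a N3 scoring epoch
  mid <- ((e3 - 1) * 30 + 12) * fs + seq_len(2 * fs)
  mask[mid] <- TRUE
  es2 <- extract_stage_epochs(rec, h, "N3", mask)
  expect_equal(sleeptopo:::n_epochs(es2), 49)

  # absent stage: empty set, not an error
  es3 <- extract_stage_epochs(rec, h, "N1")
  expect_equal(sleeptopo:::n_epochs(es3), 0)

  # sample conservation: retained + dropped subepochs tile the stage exactly
  expect_equal(sleeptopo:::n_epochs(es2) + sum(mask) / (2 * fs) * 1,
               sum(h$stage == "N3") * 5)
  # provenance addresses only N3 scoring epochs, each slot at most once
  expect_true(all(h$stage[es2$provenance$source_epoch] == "N3"))
  expect_false(any(duplicated(es2$provenance[, c("source_epoch", "slot")])))
})

test_that("pre-sleep wake selection applies the window and the 5-min rule", {
  fs <- 100
  m <- make_montage(8)
  # 30 min wake then sleep: window 10-50 min before onset keeps 20 min
  h <- hypnogram(c(rep("W", 60), rep("N1", 2), rep("N2", 38)))
  n <- nrow(h) * 30 * fs
  rec <- eeg_recording(matrix(rnorm(8 * n), 8), fs, m)
  w <- select_presleep_wake(rec, h)
  expect_false(w$excluded)
  expect_equal(w$onset_epoch, 61)
  expect_equal(sleeptopo:::n_epochs(w$epochs), 20 * 10)   # 20 min x 10 per min
  expect_equal(w$epochs$stage, "wake_presleep")

  # only 12 min of wake: 2 min fall in the window -> excluded
  h2 <- hypnogram(c(rep("W", 24), rep("N2", 76)))
  rec2 <- eeg_recording(matrix(rnorm(8 * nrow(h2) * 30 * fs), 8), fs, m)
  w2 <- select_presleep_wake(rec2, h2)
  expect_true(w2$excluded)
  expect_lt(w2$clean_minutes, 5)

  # no wake at all -> excluded
  h3 <- hypnogram(rep("N2", 100))
  rec3 <- eeg_recording(matrix(rnorm(8 * nrow(h3) * 30 * fs), 8), fs, m)
  expect_true(select_presleep_wake(rec3, h3)$excluded)
})
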