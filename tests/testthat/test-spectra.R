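# Welch estimator: analytic sine/white-noise oracles, consistency, band and
# bin aggregation, z-scoring.

make_epochs <- function(x, fs, m) {
  h <- hypnogram(rep("N3", ncol(x) / (30 * fs)))
  extract_stage_epochs(eeg_recording(x, fs, m), h, "N3")
}

test_that("a pure sine integrates to amplitude^2/2 and white noise is flat", {
  fs <- 120
  m <- make_montage(8)
  n <- 20 * 30 * fs
  tt <- seq(0, n / fs - 1 / fs, by = 1 / fs)
  A <- 25
  set.seed(1)
  x <- matrix(rnorm(8 * n, sd = 10), 8)
  x[1, ] <- A * sin(2 * pi * 9 * tt)
  psd <- welch_psd(make_epochs(x, fs, m))

  total <- sum(psd$power[1, ]) * psd$bin_width
  expect_lt(abs(total - A^2 / 2) / (A^2 / 2), 0.05)

  # white noise with variance sigma^2: density ~ sigma^2 / Nyquist
  level <- mean(psd$power[2, ])
  expect_lt(abs(level - 100 / (fs / 2)) / (100 / (fs / 2)), 0.1)
  # flat within 10% across the support (averaged over bins in coarse thirds)
  thirds <- split(psd$power[2, ], cut(seq_along(psd$freq), 3))
  expect_lt(diff(range(vapply(thirds, mean, 0))) / level, 0.1)

  # zero signal: all-zero PSD
  z <- welch_psd(make_epochs(matrix(0, 8, n), fs, m))
  expect_equal(max(z$power), 0)
  # empty epoch set errors
  h <- hypnogram(rep("N3", 20))
  rec <- eeg_recording(x, fs, m)
  expect_error(welch_psd(extract_stage_epochs(rec, h, "R")), "no data")
})

test_that("Welch variance shrinks like 1/n_epochs", {
  fs <- 120
  m <- make_montage(8)
  set.seed(2)
  band_est <- function(n_ep) {
    replicate(30, {
      x <- matrix(rnorm(8 * n_ep * 30 * fs), 8)
      psd <- welch_psd(make_epochs(x, fs, m))
      mean(psd$power[1, psd$freq >= 4 & psd$freq < 8])
    })
  }
  v2 <- var(band_est(2))
  v8 <- var(band_est(8))
  ratio <- v2 / v8
  # ~4 expected; the variance-ratio estimate itself is noisy at 30 reps
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 12)
})

test_that("band power uses half-open bins; bands and 1-Hz bins agree", {
  fs <- 120
  m <- make_montage(8)
  set.seed(3)
  x <- matrix(rnorm(8 * 10 * 30 * fs, sd = 15), 8)
  psd <- welch_psd(make_epochs(x, fs, m))

  bp <- band_power(psd)
  expect_true(all(c("subject", "stage", "channel", "band", "value",
                    "normalization") %in% names(bp)))
  # adjacent bands never double-count a PSD bin
  sel_swa <- psd$freq >= 1 & psd$freq < 4
  sel_theta <- psd$freq >= 4 & psd$freq < 8
  expect_equal(sum(sel_swa & sel_theta), 0)
  expect_equal(bp$value[bp$band == "swa" & bp$channel == "E001"],
               mean(psd$power[1, sel_swa]))

  # constant PSD: every band equals the constant, all 1-Hz bins equal
  psd_c <- psd
  psd_c$power[] <- 3.5
  bp_c <- band_power(psd_c)
  expect_true(all(abs(bp_c$value - 3.5) < 1e-12))
  bins_c <- one_hz_bins(psd_c)
  expect_true(all(abs(bins_c$value - 3.5) < 1e-12))

  # band value equals the weighted mean of its exactly-aligned 1-Hz bins
  expect_error(band_power(psd, tibble::tibble(band = "x", lo = 80, hi = 90)),
               "support")
})

test_that("a 6 Hz sine puts theta far above alpha, and a 1 Hz sine slow above fast SWA", {
  fs <- 120
  m <- make_montage(8)
  n <- 10 * 30 * fs
  tt <- seq(0, n / fs - 1 / fs, by = 1 / fs)
  x <- matrix(rnorm(8 * n, sd = 1), 8)
  x[1, ] <- x[1, ] + 40 * sin(2 * pi * 6 * tt)
  bp <- band_power(welch_psd(make_epochs(x, fs, m)))
  theta <- bp$value[bp$band == "theta" & bp$channel == "E001"]
  alpha <- bp$value[bp$band == "alpha" & bp$channel == "E001"]
  expect_gt(theta / alpha, 10)

  x2 <- matrix(rnorm(8 * n, sd = 1), 8)
  x2[1, ] <- x2[1, ] + 40 * sin(2 * pi * 1 * tt)
  bp2 <- band_power(welch_psd(make_epochs(x2, fs, m)),
                    canonical_bands(swa_split = TRUE))
  slow <- bp2$value[bp2$band == "swa_slow" & bp2$channel == "E001"]
  fast <- bp2$value[bp2$band == "swa_fast" & bp2$channel == "E001"]
  expect_gt(slow / fast, 10)
})

test_that("z-scoring standardizes per band and is idempotent and affine-invariant", {
  set.seed(4)
  map <- tibble::tibble(
    subject = "S01", stage = "N3", cycle = NA_integer_,
    channel = rep(sprintf("E%03d", 1:16), 2),
    band = rep(c("swa", "theta"), each = 16),
    value = c(rlnorm(16, 2), rlnorm(16, 1)),
    normalization = "absolute"
  )
  z <- zscore_channels(map)
  agg <- dplyr::summarise(dplyr::group_by(z, band),
                          m = mean(value), s = sd(value))
  expect_true(all(abs(agg$m) < 1e-9))
  expect_true(all(abs(agg$s - 1) < 1e-9))

  z2 <- zscore_channels(z)
  expect_equal(z2$value, z$value, tolerance = 1e-9)

  shifted <- dplyr::mutate(map, value = 5 * value + 11)
  expect_equal(zscore_channels(shifted)$value, z$value, tolerance = 1e-9)

  flat <- dplyr::mutate(map, value = 1)
  expect_error(zscore_channels(flat), "zero channel variance")
})

test_that("per-cycle power recovers an injected decline and flags missing stages", {
  fs <- 100
  m <- make_montage(8)
  # 2 cycles with N3, third cycle without N3
  st <- c(rep("W", 20),
          rep("N2", 16), rep("N3", 20), rep("R", 10),
          rep("N2", 16), rep("N3", 20), rep("R", 10),
          rep("N2", 36), rep("R", 10))
  h <- hypnogram(st)
  n <- nrow(h) * 30 * fs
  set.seed(5)
  x <- matrix(rnorm(8 * n, sd = 5), 8)
  # scale N3 amplitude by cycle: power ratio 0.64 = amplitude 0.8
  n3 <- which(h$stage == "N3")
  cyc2 <- n3[21:40]
  for (e in cyc2) {
    idx <- ((e - 1) * 30 * fs + 1):(e * 30 * fs)
    x[, idx] <- x[, idx] * 0.8
  }
  rec <- eeg_recording(x, fs, m)
  cycles <- detect_sleep_cycles(h)
  expect_equal(nrow(cycles), 3)
  cm <- per_cycle_power(rec, h, cycles, "N3",
                        tibble::tibble(band = "all", lo = 1, hi = 40))
  expect_setequal(unique(cm$cycle), c(1, 2))
  expect_equal(attr(cm, "missing_cycles"), 3L)
  ratio <- mean(cm$value[cm$cycle == 2]) / mean(cm$value[cm$cycle == 1])
  expect_gt(ratio, 0.54)
  expect_lt(ratio, 0.74)
})
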