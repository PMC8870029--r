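# Synthetic cohort generator: determinism, effect locality, calibration of
# the injected effect, covariate coupling, and map/signal consistency.

small_spec <- function(...) {
  args <- list(n_affected = 3, n_control = 3, n_channels = 16,
               sampling_rate = 100, n_cycles = 2, wake_minutes = 12,
               bad_channel_rate = 0, artifact_rate = 0, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_affected = 0), "positive")
  expect_error(cohort_spec(effect_band = c(10, 3)), "increasing")
  expect_error(cohort_spec(effect_band = c(0.1, 10)), "0.5")
  expect_error(cohort_spec(cycle_decay = c(affected = 1.2, control = 0.8)),
               "0, 1")
  expect_error(cohort_spec(covariate_correlations = c(age = -1.5, tst = 0.5)),
               "-1, 1")
})

test_that("identical spec yields identical recordings and tables", {
  sp <- small_spec()
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$subject_table, c2$subject_table)
  expect_identical(c1$subjects[[1]]$recording$data,
                   c2$subjects[[1]]$recording$data)
  expect_identical(c1$subjects[[4]]$hypnogram$stage,
                   c2$subjects[[4]]$hypnogram$stage)
})

test_that("group effect is confined to NREM epochs, ROI channels and the band", {
  sp <- small_spec(effect_size_d = 1.2)
  m <- make_montage(16)
  h <- simulate_hypnogram(2, seed = 3)
  aff <- simulate_recording(sp, "affected", h, m, seed = 21)
  ctl <- simulate_recording(sp, "control", h, m, seed = 21)
  comp <- attr(aff, "components")
  fs <- sp$sampling_rate
  roi_rows <- which(m$channel %in% comp$roi)

  idx_of <- function(stages) {
    e <- which(h$stage %in% stages)
    as.vector(vapply(e, function(k) ((k - 1) * 30 * fs + 1):(k * 30 * fs),
                     numeric(30 * fs)))
  }
  d <- abs(aff$data - ctl$data)
  expect_equal(max(d[, idx_of(c("R", "W"))]), 0)         # REM/wake untouched
  expect_equal(max(d[-roi_rows, idx_of(c("N2", "N3"))]), 0)  # off-ROI untouched
  expect_gt(mean(d[roi_rows, idx_of("N3")]), 0)

  # spectral confinement: affected/control PSD ratio ~1 outside the band
  es_a <- extract_stage_epochs(aff, h, "N3")
  es_c <- extract_stage_epochs(ctl, h, "N3")
  pa <- welch_psd(es_a); pc <- welch_psd(es_c)
  rat <- colMeans(pa$power[roi_rows, , drop = FALSE]) /
    colMeans(pc$power[roi_rows, , drop = FALSE])
  inband <- pc$freq >= 3.2 & pc$freq < 9.8
  outband <- pc$freq > 13 & pc$freq < 40
  expect_gt(mean(rat[inband]), 1.2)
  expect_lt(abs(mean(rat[outband]) - 1), 0.05)
})

test_that("a zero effect size leaves groups statistically indistinguishable", {
  diffs <- sapply(1:60, function(s) {
    sp <- cohort_spec(n_affected = 6, n_control = 6, n_channels = 16,
                      effect_size_d = 0,
                      covariate_correlations = c(age = 0, tst = 0),
                      seed = 3000 + s)
    pc <- simulate_power_cohort(sp)
    r <- roi_mean(pc$maps, pc$roi)
    aff <- pc$subject_table$group[match(r$subject, pc$subject_table$subject)]
    mean(r$value[aff == "affected"]) - mean(r$value[aff == "control"])
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("the injected per-channel effect realizes the target d", {
  # moderate Monte-Carlo at map level: mean realized per-channel d near 0.7
  m <- make_montage(32)
  roi <- select_roi_channels(m, 10)
  dvals <- sapply(1:40, function(s) {
    sp <- cohort_spec(n_channels = 32, effect_region = roi, seed = 4000 + s)
    pc <- simulate_power_cohort(sp)
    w <- tidyr::pivot_wider(pc$maps, names_from = channel,
                            values_from = value)
    aff <- pc$subject_table$group[match(w$subject,
                                        pc$subject_table$subject)] == "affected"
    mean(vapply(roi, function(ch) {
      x <- w[[ch]][aff]; y <- w[[ch]][!aff]
      sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
        (length(x) + length(y) - 2)
      (mean(x) - mean(y)) / sqrt(sp2)
    }, numeric(1)))
  })
  expect_lt(abs(mean(dvals) - 0.7), 0.25)
})

test_that("covariates recover the configured rank correlations", {
  rhos <- sapply(1:25, function(s) {
    sp <- cohort_spec(n_channels = 32, seed = 5000 + s)
    pc <- simulate_power_cohort(sp)
    r <- roi_mean(pc$maps, pc$roi)
    st <- pc$subject_table[match(r$subject, pc$subject_table$subject), ]
    c(age = cor(st$age, r$value, method = "spearman"),
      tst = cor(st$tst_estimate, r$value, method = "spearman"))
  })
  expect_gt(median(rhos["age", ]), -0.7)
  expect_lt(median(rhos["age", ]), -0.3)
  expect_gt(median(rhos["tst", ]), 0.3)
  expect_lt(median(rhos["tst", ]), 0.7)
})

test_that("REM-only maps show no systematic group effect", {
  # NREM-specific injection: REM band maps of affected vs control are null
  tvals <- sapply(1:15, function(s) {
    sp <- cohort_spec(n_affected = 10, n_control = 10, n_channels = 16,
                      covariate_correlations = c(age = 0, tst = 0),
                      seed = 6000 + s)
    pc <- simulate_power_cohort(sp, stage = "R")
    cs <- channel_stat(pc$maps, pc$subject_table)
    mean(abs(cs$t))
  })
  # mean |t| for df=18 null is ~0.86; allow generous sampling slack
  expect_lt(mean(tvals), 1.1)
  expect_gt(mean(tvals), 0.6)
})

test_that("signal-level Welch maps agree with the latent map model", {
  # the same latent gains drive both paths: per-channel band power computed
  # from synthesized signals correlates strongly with the latent gains
  sp <- small_spec(effect_size_d = 0)
  m <- make_montage(16)
  h <- simulate_hypnogram(2, seed = 8)
  gain <- stats::setNames(seq(-0.5, 0.5, length.out = 16), m$channel)
  rec <- simulate_recording(sp, "control", h, m, seed = 9,
                            channel_log_gain = gain)
  psd <- welch_psd(extract_stage_epochs(rec, h, "N3"))
  bp <- band_power(psd, tibble::tibble(band = "b", lo = 3, hi = 10))
  # per-bin biological noise (sigma_bin) bounds the attainable correlation
  expect_gt(cor(log(bp$value), gain), 0.8)
})

test_that("artifact and bad-channel injection leave recoverable ground truth", {
  sp <- small_spec(artifact_rate = 0.5, bad_channel_rate = 0.05,
                   n_channels = 64)
  m <- make_montage(64)
  h <- simulate_hypnogram(1, seed = 5)
  rec <- simulate_recording(sp, "control", h, m, seed = 31)
  comp <- attr(rec, "components")
  expect_gt(nrow(comp$artifacts), 0)
  # injected transients are caught by the bad-segment rule
  mask <- mark_bad_segments(rec, 400)
  hit <- vapply(seq_len(nrow(comp$artifacts)), function(i) {
    any(mask[comp$artifacts$start[i]:comp$artifacts$end[i]])
  }, logical(1))
  expect_true(mean(hit) > 0.8)
  # injected bad channels are flagged
  if (length(comp$bad_channels)) {
    found <- detect_bad_channels(rec, 3)
    expect_true(all(comp$bad_channels %in% found))
  }
})
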