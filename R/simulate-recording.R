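#' Synthesize one night of multichannel EEG
#'
#' Builds a recording epoch by epoch in the frequency domain: a 1/f^alpha
#' Gaussian background shaped by stage-gated oscillatory bumps (slow waves
#' in N3, sigma spindles in N2, alpha in wake), per-channel amplitude gains
#' from the latent log-power model, a multiplicative group effect confined
#' to NREM epochs, effect-region channels and the effect band, an
#' exponential decline of sub-10-Hz power across sleep cycles, plus injected
#' high-amplitude artifact transients and flat/noisy bad channels. Random
#' phases are drawn per epoch, so epochs are stationary within stage;
#' epoch boundaries are not phase-continuous.
#'
#' The injected effect consumes no random numbers: two calls differing only
#' in `group` (or in `spec$effect_size_d`) produce signals that are
#' *identical* outside the NREM/effect-region/effect-band intersection,
#' which makes the locality of the injection directly testable.
#'
#' @param spec A [cohort_spec()].
#' @param group `"affected"` or `"control"`.
#' @param hypnogram A [hypnogram()] (see [simulate_hypnogram()]).
#' @param montage An `eeg_montage` with `spec$n_channels` rows.
#' @param covariates Optional one-row covariate tibble stored on the result;
#'   covariate coupling to ROI power is realized at cohort level through the
#'   latent channel gains (see [simulate_cohort()]).
#' @param seed Integer seed for this subject's signal draws.
#' @param channel_log_gain Optional per-channel latent log-power gain
#'   (defaults to a fresh draw from the spec's variance decomposition).
#' @param subject_id Identifier stamped on the recording.
#' @return An `eeg_recording` with attribute `components` (a list with the
#'   latent gains, effect parameters, artifact ground truth and bad-channel
#'   ground truth).
#' @export
simulate_recording <- function(spec, group, hypnogram, montage,
                               covariates = NULL, seed = 1,
                               channel_log_gain = NULL,
                               subject_id = "S000") {
  validate_montage(montage)
  stopifnot(nrow(montage) == spec$n_channels,
            group %in% c("affected", "control"))
  fs <- spec$sampling_rate
  nch <- nrow(montage)
  ep_len <- epoch_length_s(hypnogram)
  ns_ep <- ep_len * fs
  n_ep <- nrow(hypnogram)
  roi <- default_effect_region(spec, montage)
  in_roi <- montage$channel %in% roi
  delta <- if (group == "affected") {
    effect_log_gain(spec$effect_size_d, band_log_sd(spec),
                    spec$n_affected, spec$n_control)
  } else 0
  decay <- spec$cycle_decay
  if (is.null(names(decay))) names(decay) <- c("affected", "control")[seq_along(decay)]
  gdecay <- decay[[group]]

  cycles <- detect_sleep_cycles(hypnogram)
  cycle_of <- rep(NA_integer_, n_ep)
  for (k in seq_len(nrow(cycles))) {
    cycle_of[cycles$nrem_start[k]:cycles$nrem_end[k]] <- cycles$cycle[k]
  }

  # rFFT grid for one scoring epoch
  kk <- seq_len(ns_ep %/% 2 - 1)
  f <- kk * fs / ns_ep
  bin_of <- pmin(40L, pmax(1L, as.integer(round(f))))
  in_band <- f >= spec$effect_band[1] & f < spec$effect_band[2]
  sub10 <- f < 10

  withr::with_seed(seed, {
    if (is.null(channel_log_gain)) {
      Ls <- spatial_factor(montage, spec$spatial_scale)
      channel_log_gain <- stats::rnorm(1, 0, spec$sigma_global) +
        as.vector(Ls %*% stats::rnorm(nch)) * spec$sigma_spatial +
        stats::rnorm(nch, 0, spec$sigma_channel)
      names(channel_log_gain) <- montage$channel
    }
    bin_noise <- matrix(stats::rnorm(nch * 40, 0, spec$sigma_bin), nch, 40)

    data <- matrix(0, nch, n_ep * ns_ep)
    for (e in seq_len(n_ep)) {
      stg <- hypnogram$stage[e]
      base <- stage_spectrum(f, stg, spec$alpha)
      w_eff <- 0
      logdecay <- 0
      if (stg %in% c("N1", "N2", "N3") && !is.na(cycle_of[e])) {
        cyc <- min(cycle_of[e], length(spec$effect_cycle_weights))
        w_eff <- spec$effect_cycle_weights[cyc]
        logdecay <- (cycle_of[e] - 1) * log(gdecay)
      }
      inject <- stg %in% c("N1", "N2", "N3")
      for (c in seq_len(nch)) {
        logp <- log(base) + channel_log_gain[c] + bin_noise[c, bin_of] +
          logdecay * sub10
        if (inject && in_roi[c] && delta != 0) {
          logp <- logp + delta * w_eff * in_band
        }
        amp <- sqrt(exp(logp) * fs * ns_ep / 4)
        z <- complex(real = stats::rnorm(length(kk)),
                     imaginary = stats::rnorm(length(kk)))
        X <- c(0, amp * z, 0, Conj(rev(amp * z)))
        data[c, ((e - 1) * ns_ep + 1):(e * ns_ep)] <-
          Re(stats::fft(X, inverse = TRUE)) / ns_ep
      }
    }

    # high-amplitude transients hitting the majority of channels
    artifacts <- list()
    p_art <- min(1, spec$artifact_rate * ep_len / 60)
    for (e in seq_len(n_ep)) {
      if (stats::runif(1) >= p_art) next
      dur <- 2 * fs
      start <- (e - 1) * ns_ep + sample.int(ns_ep - dur, 1)
      hit <- sort(sample.int(nch, ceiling(0.7 * nch)))
      tt <- seq_len(dur) / fs
      burst <- 600 * sin(2 * pi * 2 * tt) * exp(-((tt - 1) / 0.6)^2)
      data[hit, (start + 1):(start + dur)] <-
        data[hit, (start + 1):(start + dur)] +
        matrix(burst, length(hit), dur, byrow = TRUE)
      artifacts[[length(artifacts) + 1]] <- c(start + 1, start + dur)
    }

    # flat or noisy bad channels
    n_bad <- stats::rbinom(1, nch, spec$bad_channel_rate)
    bad_channels <- character()
    if (n_bad > 0) {
      bi <- sample.int(nch, n_bad)
      for (j in seq_along(bi)) {
        if (j %% 2 == 1) {
          data[bi[j], ] <- data[bi[j], ] * 0.01           # flat
        } else {
          data[bi[j], ] <- data[bi[j], ] +
            stats::rnorm(ncol(data), 0, 150)              # noisy
        }
      }
      bad_channels <- montage$channel[sort(bi)]
    }

    rec <- eeg_recording(data, fs, montage, subject_id = subject_id,
                         reference = "vertex")
    attr(rec, "components") <- list(
      channel_log_gain = channel_log_gain, delta = delta, roi = roi,
      effect_band = spec$effect_band, cycle_of = cycle_of,
      artifacts = if (length(artifacts)) {
        m <- do.call(rbind, artifacts)
        tibble::tibble(start = m[, 1], end = m[, 2])
      } else tibble::tibble(start = integer(), end = integer()),
      bad_channels = bad_channels,
      covariates = covariates
    )
    rec
  })
}

#' Simulate a full synthetic cohort of overnight recordings
#'
#' Draws the latent cohort structure (groups, channel gains, covariates
#' coupled to latent ROI power by the Gaussian copula), then synthesizes
#' one hypnogram and one multichannel recording per subject. Everything is
#' a deterministic function of `spec` (including `spec$seed`).
#'
#' Signal-level cohorts are intended for moderate sizes (the default
#' full-scale spec describes the target study design; pipeline tests
#' typically use fewer channels and subjects). For cohort-scale statistical
#' studies use [simulate_power_cohort()], which samples the same latent
#' model directly at map level.
#'
#' @param spec A [cohort_spec()].
#' @param montage Optional montage (default `make_montage(spec$n_channels)`).
#' @return A `sleep_cohort`: list with `subjects` (each a list of
#'   `subject_id`, `group`, `recording`, `hypnogram`, `covariates`),
#'   `subject_table`, `montage`, `roi`.
#' @export
simulate_cohort <- function(spec, montage = NULL) {
  if (is.null(montage)) montage <- make_montage(spec$n_channels)
  lat <- latent_cohort(spec, montage)
  st <- lat$subject_table
  subjects <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    h <- simulate_hypnogram(spec$n_cycles, seed = lat$subject_seeds[i],
                            wake_minutes = spec$wake_minutes,
                            nrem_minutes = spec$nrem_minutes,
                            rem_minutes = spec$rem_minutes)
    rec <- simulate_recording(
      spec, st$group[i], h, montage,
      covariates = st[i, setdiff(names(st), c("subject", "group"))],
      seed = lat$subject_seeds[i] + 1L,
      channel_log_gain = lat$channel_gain[i, ],
      subject_id = st$subject[i]
    )
    subjects[[i]] <- list(subject_id = st$subject[i], group = st$group[i],
                          recording = rec, hypnogram = h,
                          covariates = st[i, ])
  }
  structure(list(subjects = subjects, subject_table = st,
                 montage = montage, roi = lat$roi),
            class = "sleep_cohort")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  cat("Synthetic sleep cohort:", length(x$subjects), "subjects (",
      sum(x$subject_table$group == "affected"), "affected /",
      sum(x$subject_table$group == "control"), "control ),",
      nrow(x$montage), "channels\n")
  invisible(x)
}
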