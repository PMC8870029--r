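# Latent log-power model shared by the map-level sampler and the signal
# synthesizer. Per subject i, channel c, frequency bin f:
#
#   log P[i,c,f] = log B_stage(f) + g_i + s_i(c) + e_i(c) + eps[i,c,f]
#                  + delta * 1[affected, c in ROI, f in effect band]
#                  + (cycle-1) * log(decay_group)   (sub-10-Hz, NREM)
#
# g_i     global amplitude gain            ~ N(0, sigma_global^2)
# s_i(c)  smooth scalp field               GP, Gaussian kernel(spatial_scale)
# e_i(c)  independent channel gain         ~ N(0, sigma_channel^2)
# eps     per-bin measurement noise        ~ N(0, sigma_bin^2)

# lower-triangular factor of the smooth-field covariance on the montage
spatial_factor <- function(montage, scale) {
  arc <- geodesic_distances(montage_positions(montage))
  K <- exp(-arc^2 / (2 * scale^2))
  diag(K) <- diag(K) + 1e-8
  t(chol(K))
}

# mean band-limited background power spectral density (uV^2/Hz) for one
# sleep stage: 1/f^alpha background plus stage-gated oscillatory bumps
# (slow waves in N3, sigma spindles in N2, alpha in wake)
stage_spectrum <- function(freq, stage, alpha = 1.5, level = 230) {
  base <- level * pmax(freq, 0.5)^(-alpha)
  bump <- switch(stage,
    N3 = 8 * exp(-(freq - 1.5)^2 / 2),
    N2 = 1.5 * exp(-(freq - 1.5)^2 / 2) + 2.5 * exp(-(freq - 14)^2 / 4.5),
    N1 = 0.8 * exp(-(freq - 5)^2 / 8),
    W = 3 * exp(-(freq - 10)^2 / 2),
    R = 1.2 * exp(-(freq - 5)^2 / 8),
    0
  )
  base * (1 + bump)
}

# subject-level latent structure: groups, channel log-gains, covariates
# coupled to the latent ROI deviation through a Gaussian copula
latent_cohort <- function(spec, montage) {
  n <- spec$n_affected + spec$n_control
  roi <- default_effect_region(spec, montage)
  nch <- nrow(montage)
  Ls <- spatial_factor(montage, spec$spatial_scale)
  withr::with_seed(spec$seed, {
    group <- c(rep("affected", spec$n_affected),
               rep("control", spec$n_control))
    g <- stats::rnorm(n, 0, spec$sigma_global)
    smooth <- t(Ls %*% matrix(stats::rnorm(nch * n), nch, n)) *
      spec$sigma_spatial
    chan <- matrix(stats::rnorm(n * nch, 0, spec$sigma_channel), n, nch)
    gain <- g + smooth + chan
    colnames(gain) <- montage$channel

    # Gaussian copula: covariates conditioned on the subject's latent ROI
    # deviation (centred within group, so groups stay age-matched). The
    # latent Pearson correlation is 2 sin(pi rho_S / 6) to hit the target
    # *rank* correlation, divided by the analytic attenuation the measured
    # ROI power suffers from the group effect itself (the injected log-gain
    # adds group-label variance the covariates do not share).
    delta <- effect_log_gain(spec$effect_size_d, band_log_sd(spec),
                             spec$n_affected, spec$n_control)
    r <- rowMeans(gain[, roi, drop = FALSE])
    r_centred <- r - stats::ave(r, group)
    z_r <- r_centred / stats::sd(r_centred)
    p_aff <- spec$n_affected / n
    atten <- stats::sd(r_centred) /
      sqrt(stats::var(r_centred) + delta^2 * p_aff * (1 - p_aff))
    rho <- 2 * sin(pi * spec$covariate_correlations / 6) / atten
    rho <- pmax(pmin(rho, 0.98), -0.98)
    z_age <- rho[["age"]] * z_r + sqrt(1 - rho[["age"]]^2) * stats::rnorm(n)
    z_tst <- rho[["tst"]] * z_r + sqrt(1 - rho[["tst"]]^2) * stats::rnorm(n)
    subject_table <- tibble::tibble(
      subject = sprintf("S%03d", seq_len(n)),
      group = group,
      age = round(pmin(13.9, pmax(7.8, 10.4 + 1.9 * z_age)), 2),
      tst_estimate = round(420 + 55 * z_tst, 1),
      mslt_latency = round(pmax(1, 12 + 3.5 * stats::rnorm(n)), 1),
      conners_global = round(ifelse(group == "affected",
                                    76 + 10.8 * stats::rnorm(n),
                                    45 + 8 * stats::rnorm(n))),
      wisc_global = round(100 + 9 * stats::rnorm(n))
    )
    subject_seeds <- sample.int(2^30, n)
    list(subject_table = subject_table, channel_gain = gain, roi = roi,
         subject_seeds = subject_seeds, delta = delta)
  })
}

#' Sample a cohort of power maps directly from the generator's latent model
#'
#' Draws subject x channel x frequency-bin band power for one sleep stage
#' from the latent lognormal model (no time-domain signals involved), along
#' with the derived quantities the group analyses consume: effect-band power
#' maps, channel-averaged spectra, per-cycle ROI power, and the coupled
#' subject covariate table. This is the sampler used for statistical
#' calibration studies (type-I error, parameter recovery), where thousands
#' of cohorts are needed; [simulate_cohort()] synthesizes the same model as
#' raw multichannel signals.
#'
#' @param spec A [cohort_spec()].
#' @param montage Optional `eeg_montage` (default `make_montage(spec$n_channels)`).
#' @param stage Sleep stage whose background spectrum is used (default N3).
#'   The group effect is injected for NREM stages only.
#' @param bins Frequency-bin centres in Hz.
#' @return A list with `maps` (tibble: subject, channel, value — effect-band
#'   mean power), `bin_maps` (subject, channel, freq, value), `spectra`
#'   (subject, freq, value — channel-averaged), `cycle_power` (subject,
#'   cycle, value — ROI effect-band power per sleep cycle), `subject_table`,
#'   `roi`, `delta`, `montage`.
#' @export
simulate_power_cohort <- function(spec, montage = NULL, stage = "N3",
                                  bins = 1:40) {
  if (is.null(montage)) montage <- make_montage(spec$n_channels)
  lat <- latent_cohort(spec, montage)
  st <- lat$subject_table
  n <- nrow(st)
  nch <- nrow(montage)
  nf <- length(bins)
  affected <- st$group == "affected"
  in_roi <- montage$channel %in% lat$roi
  in_band <- bins >= spec$effect_band[1] & bins < spec$effect_band[2]
  nrem <- stage %in% c("N1", "N2", "N3", "NREM")
  decay <- spec$cycle_decay
  if (is.null(names(decay))) names(decay) <- c("affected", "control")[seq_along(decay)]
  decay <- decay[c("affected", "control")]

  withr::with_seed(spec$seed + 1L, {
    base <- log(stage_spectrum(bins, if (stage == "NREM") "N3" else stage,
                               spec$alpha))
    logp <- array(stats::rnorm(n * nch * nf, 0, spec$sigma_bin),
                  dim = c(n, nch, nf))
    logp <- logp + array(rep(base, each = n * nch), dim = dim(logp))
    logp <- logp + array(rep(lat$channel_gain, nf), dim = dim(logp))
    if (nrem && lat$delta != 0) {
      inject <- outer(affected, in_roi) %o% in_band
      logp <- logp + lat$delta * inject
    }
    p <- exp(logp)

    band_map <- apply(p[, , in_band, drop = FALSE], c(1, 2), mean)
    maps <- tibble::tibble(
      subject = rep(st$subject, nch),
      channel = rep(montage$channel, each = n),
      value = as.vector(band_map)
    )
    bin_maps <- tibble::tibble(
      subject = rep(st$subject, nch * nf),
      channel = rep(rep(montage$channel, each = n), nf),
      freq = rep(bins, each = n * nch),
      value = as.vector(p)
    )
    chan_avg <- apply(p, c(1, 3), mean)
    spectra <- tibble::tibble(
      subject = rep(st$subject, nf),
      freq = rep(bins, each = n),
      value = as.vector(chan_avg)
    )

    # per-cycle ROI power: homeostatic exponential decline plus the
    # cycle-weighted group elevation and cycle-level noise
    base_band <- mean(stage_spectrum(bins[in_band],
                                     if (stage == "NREM") "N3" else stage,
                                     spec$alpha))
    r <- rowMeans(lat$channel_gain[, in_roi, drop = FALSE])
    k <- seq_len(spec$n_cycles)
    w <- spec$effect_cycle_weights
    cyc <- expand.grid(i = seq_len(n), cycle = k)
    gdecay <- ifelse(affected[cyc$i], decay[["affected"]], decay[["control"]])
    mu <- log(base_band) + r[cyc$i] + (cyc$cycle - 1) * log(gdecay) +
      lat$delta * w[cyc$cycle] * affected[cyc$i]
    cycle_power <- tibble::tibble(
      subject = st$subject[cyc$i],
      cycle = cyc$cycle,
      value = exp(mu + stats::rnorm(nrow(cyc), 0, spec$sigma_cycle))
    )

    list(maps = maps, bin_maps = bin_maps, spectra = spectra,
         cycle_power = cycle_power, subject_table = st, roi = lat$roi,
         delta = lat$delta, montage = montage)
  })
}
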