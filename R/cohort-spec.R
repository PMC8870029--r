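#' Specification of a synthetic sleep-EEG cohort
#'
#' Collects every parameter of the synthetic-cohort generator: design sizes,
#' the localized group effect, the homeostatic cycle decline, covariate
#' coupling, artifact rates, and the variance decomposition of the latent
#' log-power model. Defaults reproduce the study conditions the analysis
#' pipeline targets: 30 affected vs 23 control subjects, a centro-posterior
#' 3-10 Hz NREM effect of standardized size 0.7 sparing frontopolar sensors,
#' an exponential decline of sub-10-Hz power across the first three sleep
#' cycles that is maximal for the group effect in cycle 1, and clinical
#' covariates rank-correlated with ROI power (age -0.5, estimated total sleep
#' time +0.5).
#'
#' The latent model, shared by the map-level sampler and the signal
#' synthesizer, writes per-subject log band power as a sum of a global
#' amplitude gain (`sigma_global`), a spatially smooth scalp field
#' (`sigma_spatial`, Gaussian kernel with geodesic length `spatial_scale`
#' radians), an independent per-channel gain (`sigma_channel`, dominating, as
#' electrode-level impedance differences do), and per-bin measurement noise
#' (`sigma_bin`). `effect_size_d` is the targeted standardized group
#' difference of band power at each ROI channel; the corresponding
#' multiplicative log-gain is solved in closed form under this lognormal
#' model (see [effect_log_gain()]).
#'
#' @param n_affected,n_control Group sizes.
#' @param n_channels Number of sensors (8-256).
#' @param sampling_rate Sampling rate in Hz (integer).
#' @param n_cycles Number of sleep cycles to simulate.
#' @param effect_band Frequency interval (Hz, half-open) carrying the group
#'   effect; must lie within 0.5-45 Hz.
#' @param effect_region Channel labels carrying the effect, or `NULL` to use
#'   all centro-posterior (central/parietal/occipital) channels of the
#'   montage, sparing frontopolar sensors.
#' @param effect_size_d Target standardized group difference (per ROI
#'   channel) in effect-band NREM power; 0 disables the effect.
#' @param cycle_decay Per-cycle multiplicative decline of sub-10-Hz power,
#'   named per group (`affected`, `control`), each in (0, 1).
#' @param effect_cycle_weights Relative strength of the group effect in each
#'   cycle (recycled/truncated to `n_cycles`); the default makes the group
#'   difference maximal in cycle 1 and fading thereafter.
#' @param covariate_correlations Target Spearman correlations of ROI power
#'   with age and parent-estimated total sleep time, each in (-1, 1).
#' @param artifact_rate Expected high-amplitude transients per minute.
#' @param bad_channel_rate Probability that a channel is bad (flat or noisy).
#' @param alpha Spectral exponent of the 1/f^alpha background.
#' @param sigma_global,sigma_spatial,spatial_scale,sigma_channel,sigma_bin,sigma_cycle
#'   Latent log-power variance decomposition (see Details).
#' @param wake_minutes,nrem_minutes,rem_minutes Approximate block durations
#'   used by [simulate_hypnogram()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return A `cohort_spec` object (a named list).
#' @export
cohort_spec <- function(n_affected = 30, n_control = 23, n_channels = 64,
                        sampling_rate = 250, n_cycles = 3,
                        effect_band = c(3, 10), effect_region = NULL,
                        effect_size_d = 0.7,
                        cycle_decay = c(affected = 0.8, control = 0.8),
                        effect_cycle_weights = c(1, 0.5, 0.25),
                        covariate_correlations = c(age = -0.5, tst = 0.5),
                        artifact_rate = 0.2, bad_channel_rate = 0.03,
                        alpha = 1.5,
                        sigma_global = 0.04, sigma_spatial = 0.10,
                        spatial_scale = 0.35, sigma_channel = 0.35,
                        sigma_bin = 0.30, sigma_cycle = 0.10,
                        wake_minutes = 25, nrem_minutes = 18,
                        rem_minutes = 6, seed = 1) {
  spec <- list(
    n_affected = as.integer(n_affected), n_control = as.integer(n_control),
    n_channels = as.integer(n_channels),
    sampling_rate = as.integer(sampling_rate),
    n_cycles = as.integer(n_cycles),
    effect_band = as.numeric(effect_band), effect_region = effect_region,
    effect_size_d = effect_size_d,
    cycle_decay = cycle_decay,
    effect_cycle_weights = rep_len(effect_cycle_weights, n_cycles),
    covariate_correlations = covariate_correlations,
    artifact_rate = artifact_rate, bad_channel_rate = bad_channel_rate,
    alpha = alpha,
    sigma_global = sigma_global, sigma_spatial = sigma_spatial,
    spatial_scale = spatial_scale, sigma_channel = sigma_channel,
    sigma_bin = sigma_bin, sigma_cycle = sigma_cycle,
    wake_minutes = wake_minutes, nrem_minutes = nrem_minutes,
    rem_minutes = rem_minutes,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_affected < 1 || n_control < 1 || n_cycles < 1) {
      stop("counts (group sizes, cycles) must be positive")
    }
    if (n_channels < 8 || n_channels > 256) stop("n_channels must be in [8, 256]")
    if (sampling_rate <= 0) stop("sampling_rate must be positive")
    if (length(effect_band) != 2 || effect_band[1] >= effect_band[2] ||
        effect_band[1] < 0.5 || effect_band[2] > 45) {
      stop("effect_band must be an increasing interval within 0.5-45 Hz")
    }
    if (any(cycle_decay <= 0 | cycle_decay >= 1)) {
      stop("cycle_decay values must lie in (0, 1)")
    }
    if (any(abs(covariate_correlations) >= 1)) {
      stop("covariate correlations must lie in (-1, 1)")
    }
    if (artifact_rate < 0 || bad_channel_rate < 0 || bad_channel_rate > 1) {
      stop("artifact/bad-channel rates out of range")
    }
  })
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_affected, "affected vs", x$n_control,
      "control;", x$n_channels, "channels @", x$sampling_rate, "Hz;",
      x$n_cycles, "cycles\n")
  cat("Effect: d =", x$effect_size_d, "in",
      paste(x$effect_band, collapse = "-"), "Hz,",
      if (is.null(x$effect_region)) "centro-posterior region"
      else paste(length(x$effect_region), "channels"),
      "| cycle decay:", paste(x$cycle_decay, collapse = "/"),
      "| seed", x$seed, "\n")
  invisible(x)
}

# log-power SD of one channel's band measurement. Per-bin noise averages out
# across the 1-Hz bins inside the band, but the average is weighted by the
# background spectrum (steep 1/f plus the slow-wave bump), so the effective
# number of independent bins is (sum w)^2 / sum w^2, not the bin count.
band_log_sd <- function(spec, bins = 1:40, stage = "N3") {
  in_band <- bins >= spec$effect_band[1] & bins < spec$effect_band[2]
  w <- stage_spectrum(bins[in_band], stage, spec$alpha)
  n_eff <- if (length(w)) sum(w)^2 / sum(w^2) else 1
  sqrt(spec$sigma_global^2 + spec$sigma_spatial^2 + spec$sigma_channel^2 +
         spec$sigma_bin^2 / n_eff)
}

#' Multiplicative log-gain realizing a target standardized effect
#'
#' Under the generator's lognormal power model a channel's band power in the
#' control group is `exp(X)` with `X ~ N(mu, sigma^2)`; in the affected group
#' it is multiplied by `exp(delta)`. This solves for the `delta` whose
#' raw-scale pooled Cohen's d equals `d`, using the lognormal moments:
#' mean ratio `exp(delta)`, group variances `exp(2 delta) v` and `v` with
#' `v = exp(sigma^2) - 1`.
#'
#' @param d Target standardized difference (may be 0 or negative).
#' @param sigma Total log-power SD of one channel measurement.
#' @param n1,n2 Group sizes entering the pooled SD.
#' @return The log-gain `delta` (0 when `d` is 0).
#' @export
effect_log_gain <- function(d, sigma, n1 = 30, n2 = 23) {
  if (d == 0) return(0)
  # pooled weights need n >= 2 per group; fall back to balanced weights
  if (n1 < 2 || n2 < 2) {
    n1 <- 2
    n2 <- 2
  }
  v <- exp(sigma^2) - 1
  f <- function(delta) {
    sp <- sqrt(((n1 - 1) * exp(2 * delta) * v + (n2 - 1) * v) / (n1 + n2 - 2))
    (exp(delta) - 1) * exp(sigma^2 / 2) / (sp * exp(sigma^2 / 2)) - d
  }
  stats::uniroot(f, c(-5, 5), tol = 1e-10)$root
}

# default centro-posterior effect region: every channel tagged central,
# parietal or occipital (frontopolar sensors are spared by construction)
default_effect_region <- function(spec, montage) {
  if (!is.null(spec$effect_region)) {
    missing <- setdiff(spec$effect_region, montage$channel)
    if (length(missing)) stop("effect_region channels not in montage: ",
                              paste(missing, collapse = ", "))
    return(spec$effect_region)
  }
  montage$channel[montage$region %in% c("central", "parietal", "occipital")]
}
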