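---
title: "Sleep power topography: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep power topography: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeptopo)
```

This vignette is the package's own account of the science it implements:
the signal-processing chain, the statistical models, the synthetic-cohort
generator that makes the whole pipeline testable, and the design decisions
taken where more than one defensible convention exists.

## The analysis problem

High-density sleep EEG studies ask whether the scalp topography of
band-limited signal power differs between two groups of subjects, whether
such differences are stage-specific (NREM N2/N3 vs REM vs pre-sleep wake),
how they evolve across successive sleep cycles (the homeostatic decline of
low-frequency power), and how they relate to clinical covariates. The
statistical difficulty is the sensor dimension: with tens to hundreds of
electrodes, per-channel testing needs family-wise control that respects the
spatial smoothness of EEG topographies. The standard answer — implemented
here — is the cluster-based permutation test on the electrode adjacency
graph.

## Signal conditioning

Each recording passes through, in order:

1. **First-order high-pass, 0.1 Hz.** A single-pole RC filter applied
   causally per channel: `y[n] = a (y[n-1] + x[n] - x[n-1])` with
   `a = RC/(RC + 1/fs)`, `RC = 1/(2π · 0.1)`. It removes DC and
   sub-0.1 Hz drift while attenuating 10 Hz activity by well under 1 %.
2. **Zero-phase FIR band-pass, 0.5–45 Hz.** A linear-phase Kaiser-window
   design (single-pass stopband ≥ 60 dB; transition 0.4 Hz below the low
   edge, 5 Hz above the high edge) applied forward and time-reversed, so the
   effective response is the squared magnitude of the design and net phase
   is exactly zero. The realization convolves with the autocorrelation of
   the design kernel via FFT with zero-padded edges; the first and last
   kernel-length samples carry the usual transients, and the order-stability
   test verifies that high-pass→band-pass and band-pass→high-pass agree to
   numerical precision once those transients have settled.
3. **Artifact masking.** The scored artifact rejection of clinical practice
   is visual; the pipeline substitutes an automatic surrogate with the same
   contract: a sample is bad when more than 50 % of channels exceed an
   amplitude threshold (default 500 µV) within a sliding 1-s window, and
   clean islands shorter than 1 s inside artifacts are absorbed. "Majority
   of channels" is operationalized as > 50 % because no sharper definition
   is standard.
4. **Bad channels.** A channel is flagged when its log total power deviates
   from the median of its graph neighbours by more than 5 robust z-units;
   flagged channels are rebuilt by spherical-spline interpolation
   (order m = 4 Legendre weighting, series truncated at degree 7, ridge
   1e-5 — the standard spline parameterization). Interpolation refuses to
   run when a quarter or more of the montage is bad.
5. **Average reference**, subtracting the instantaneous channel mean.

## Spectra, maps and cycles

Spectral analysis uses all artifact-free **6-s epochs**, taken as the five
non-overlapping subdivisions of each retained 30-s scoring epoch, aligned
to the scoring grid (alignment is a convention; overlap is not used).
Welch's averaged modified periodogram cuts each 6-s epoch into 8 Hamming
windows at 50 % overlap. Eight half-overlapping segments tile an epoch of
length `L` when the segment length is `L/4.5`, i.e. 1.33 s, giving a
frequency resolution of ≈ 0.75 Hz; segment length is floored to an integer
sample count and the 8 segment starts are spread evenly so exactly eight
segments always fit. Scaling is one-sided density (µV²/Hz): a unit-amplitude
sine integrates to 1/2 and white noise of variance σ² sits at σ²/Nyquist,
both verified against closed forms.

Band maps average density over bins whose centre lies in the **half-open**
interval `[lo, hi)`. The classical band edges touch (SWA 1–4, theta 4–8,
…), so half-open membership is what prevents a 4 Hz bin from being counted
in two bands. Band power is the *mean* density rather than the integral, so
values are comparable across bands of different width. One-hertz bins use
the same rule on `[f-0.5, f+0.5)`; the slow/fast SWA split (0.5–2.5 /
2.5–4 Hz) is available as extra bands. Normalized maps z-score the channels
within subject and band — idempotent and invariant to channel-common
affine changes, which is why multiplicative (gain-like) group effects
survive normalization while global amplitude differences do not.

**Sleep cycles** follow the conventional NREM-period/REM-period rule: an
NREM period of ≥ 15 min followed by a REM period (any duration for the
first cycle, ≥ 5 min afterwards; shorter REM runs are absorbed into the
ongoing NREM period); a final NREM period of sufficient duration without
REM is kept as an incomplete cycle, and sleep onset is the first non-wake
epoch — none of these rules is uniquely standard, so they are stated here
and frozen. Per-cycle maps restrict a stage to each cycle's NREM period;
subjects lacking the stage in a cycle are flagged and removed listwise from
the cycle ANOVA only.

Pre-sleep wakefulness is harvested from the window 10–50 min before sleep
onset; subjects retaining less than 5 clean minutes are excluded from the
wake analysis only.

## Cluster-based permutation inference

Per channel, the group comparison is an unpaired two-sided pooled-variance
*t* (df = n₁+n₂−2); with a covariate it is the *t* of the group coefficient
in `value ~ group + covariate` (df = n−3), computed by the partial
regression identity so thousands of permutations reduce to matrix algebra.
Channels with *p* below the forming threshold (0.05) are grouped into
maximal connected components of the adjacency graph, separately per sign.
The null is built by shuffling group labels (covariate values stay attached
to their subjects — the simplest scheme consistent with label
exchangeability), storing at each of the `n_permutations` iterations the
largest cluster over both signs, and taking the 95th percentile as the
critical cluster size. Permutation p-values use `(1 + exceedances)/(B + 1)`
and cannot fall below `1/(B+1)`.

Two numerical decisions deserve emphasis:

* **Tie-broken cluster size.** The electrode count is a small integer, so
  its permutation null is coarse: the exceedance probability jumps across
  the 5 % level and a conservative tie rule drives the realized family-wise
  error well below nominal. Clusters
  are therefore ordered by size with the continuous cluster mass (sum of
  |t|) as a tie-break — the comparison statistic is `size +
  mass/(1+mass)`, which never reorders clusters of different sizes but
  makes the null continuous. Measured family-wise error on null synthetic
  cohorts is ≈ 4–5 %. Plain mass is available via `statistic = "mass"`.
* **Sign handling.** The null maximum is taken across both signs, which
  controls the family-wise error for the two-sided question; the mode is
  recorded in the result object.

The adjacency graph defaults to the Delaunay triangulation of the 2-D
azimuthal projection with edges beyond 1.5× the median length pruned (rim
shortcuts removed); a symmetrized k-nearest-neighbour construction is the
fallback for degenerate geometry. The frequency-bin analogue of the test
uses the chain graph over bin centres and returns contiguous significant
ranges.

## ROI inference

The region of interest is harvested as the channels of the significant
cluster in a configured band and stage (default: 3–10 Hz in N3). ROI mean
power then enters:

* a **group × stage** and a **group × cycle mixed ANOVA**: the classical
  split-plot decomposition with the within-subject hypotheses tested on the
  unweighted (type III) grand mean, Greenhouse–Geisser ε from the pooled
  error SSP of orthonormal within-contrasts, the Huynh–Feldt value
  `((N-a+1)(k-1)ε̂ - 2) / ((k-1)(N-a-(k-1)ε̂))` clipped at 1 (exactly 1
  for two within levels), both raw and HF-corrected p reported regardless
  of ε magnitude, and partial η² = SS_effect/(SS_effect+SS_error).
  The implementation is validated against `car::Anova` on multivariate
  models as an independent oracle.
* **clinical correlations**: Spearman's ρ with the tie-aware t
  approximation, Bonferroni-corrected over the family (five tests at
  α = 0.05 give a per-test threshold of 0.01). The partial Spearman
  controlling for age is defined by rank residualization — ranks of x and y
  are each regressed on the ranks of the controls and the residuals
  correlated — one of several conventions, recorded in the output.
* summary-statistics tools (`two_sample_t`, `cohens_d_pooled`,
  `yates_chi2`) that operate on printed group means/SDs/counts, so
  published tables can be re-analysed without raw data. Both pooled and
  Welch t variants are exposed because printed demographic comparisons are
  frequently reproducible only under one of the two.

## The synthetic cohort generator

The generator exists because high-density clinical sleep EEG is, in
practice, not shared. Its defaults encode the study design the pipeline
targets: 30 affected vs 23 control subjects, 3–10 Hz NREM effect of
standardized size d = 0.7 over a centro-posterior region sparing
frontopolar sensors, three sleep cycles with a per-cycle decline of
sub-10-Hz power (decay 0.8) and a group effect maximal in cycle 1
(weights 1, 0.5, 0.25), and covariates rank-correlated with ROI power
(age −0.5, parent-estimated total sleep time +0.5).

One latent lognormal model underlies everything. Per subject *i*, channel
*c*, frequency bin *f*:

```
log P[i,c,f] = log B_stage(f) + g_i + s_i(c) + e_i(c) + ε[i,c,f]
               + δ · 1[affected, c ∈ ROI, f ∈ band]            (NREM only)
               + (cycle−1) · log(decay)                        (f < 10 Hz)
```

with `B_stage` a 1/f^1.5 background shaped by stage-gated bumps (slow
waves in N3, sigma spindles in N2, alpha in wake), a global amplitude gain
`g_i` (SD 0.04), a spatially smooth scalp field `s_i` (SD 0.10, Gaussian
kernel of geodesic length 0.35 rad), an independent per-channel gain `e_i`
(SD 0.35 — electrode-level impedance variation, deliberately the dominant
term), and per-bin variability ε (SD 0.30). The variance decomposition was
fixed once, by a design-stage power analysis, so that the model's own
calibration targets are simultaneously achievable: a d = 0.7 injection is
recovered by the cluster test and by the spectrum test in well over 80 % of
cohorts while the null family-wise error stays at 5 %. A strongly
channel-correlated decomposition (large `g_i` or long-range `s_i`) provably
breaks this — shared noise lets permutation nulls percolate into giant
clusters — so the chosen structure is a *statistically homogeneous* cohort;
real cohorts with large global amplitude variability will be harder than
the synthetic benchmark, and that is a documented limitation, not an
accident.

`effect_size_d` is defined as the standardized group difference of band
power **at each ROI channel**; the multiplicative log-gain δ is solved in
closed form from the lognormal moments (`effect_log_gain()`), using the
spectrally weighted effective number of independent bins in the band
(the steep 1/f background plus the slow-wave bump concentrate band weight,
so ~2.5 effective bins rather than 7). The ROI-*average* realizes a larger
d because channel noise averages out — when interpreting recovery results,
the per-channel definition is the one calibrated and tested.

Covariates couple through a Gaussian copula: age and TST quantiles are
conditioned on the subject's latent ROI gain (centred within group, so
groups stay age-matched), with the latent Pearson correlation
`2 sin(π ρ_S / 6)` divided by the analytic attenuation the measured power
suffers from the injected group effect. The whole-cohort Spearman
correlations land on their targets in expectation.

Two samplers share this model. `simulate_power_cohort()` draws maps,
channel-averaged spectra and per-cycle ROI power directly — thousands of
cohorts per minute, which is what the statistical calibration suites use.
`simulate_cohort()`/`simulate_recording()` synthesize actual multichannel
time series: per 30-s epoch the target spectrum is realized with random
phases (stationary within epoch; boundaries are not phase-continuous),
plus injected majority-channel artifact transients and flat/noisy bad
channels with ground truth recorded in the `components` attribute. The
injection consumes no random numbers, so two same-seed runs differing only
in group produce signals identical outside the NREM × ROI × band
intersection — the effect-locality tests rely on this. Signals are written
as 16-bit EDF over a fixed ±1000 µV physical range.

What the generator does **not** emulate: real artifact morphology (ocular,
cardiac, muscular components with their spatial signatures — only
amplitude transients), non-stationarity within stages, arousals and stage
transitions at realistic hazard rates, oscillatory events as discrete
entities (spindles are a stationary sigma bump), volume-conduction-correct
topographies, or polysomnographic auxiliary channels. Passing the recovery
suites therefore demonstrates the statistical machinery is correct and
calibrated under the stated model — not that preprocessing would cope with
every clinical artifact zoo.

## Problem sizes used by the test and acceptance suites

The statistical suites run at sizes chosen to make the Monte-Carlo
assertions sharp while keeping a full run comfortable on one CPU: type-I
calibration on 200 null cohorts (32 channels, 15 + 15 subjects, 1000
permutations), recovery on 50 cohorts at full design size (64 channels,
30 + 23) with 1000 permutations, homeostasis detection on 50 cohorts, and
signal-level tests on 8–64-channel recordings of one to three cycles at
100–120 Hz. The acceptance script uses 25-cohort batches for the recovery
rates. Exhaustive enumeration backs the permutation machinery at n₁=n₂=4
(70 assignments), where exactness can be checked literally.

## Known limitations

* The cluster test controls family-wise error per comparison; like the
  analysis it implements, no correction is applied across the band × stage
  grid of comparisons, which is exploratory by design.
* The covariate permutation scheme shuffles labels with (value, covariate)
  pairs intact; residual-permutation schemes for stronger confounding are
  out of scope.
* The mixed ANOVA handles one between and one within factor — the designs
  used here — not general factorial structures.
* EDF support covers the subset the fixtures use (uniform integer sampling
  rates, 1-s records, no annotations).
* Cycle segmentation rules and the 6-s epoch alignment are conventions;
  both are parameterized or documented above where alternatives exist.
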