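#' Analysis configuration
#'
#' Bundles every knob of the end-to-end analysis: the cohort source (a
#' fixture directory or a synthetic [cohort_spec()]), signal conditioning
#' parameters, the band/stage analysis grid, permutation-test settings, the
#' ROI harvest rule, the clinical correlation family, and the output
#' directory. See [validate_config()] for structural checks and
#' [run_full_analysis()] for execution.
#'
#' @param output_dir Directory for result files.
#' @param input_dir Directory of fixture files (see [write_fixtures()]), or
#'   `NULL` when `synthetic` is given.
#' @param synthetic A [cohort_spec()] to simulate, or `NULL`.
#' @param bands Band definition tibble.
#' @param stages Stages to map and test.
#' @param n_permutations,forming_alpha,cluster_alpha Cluster-test settings.
#' @param use_age_covariate Also run every cluster test with age as
#'   covariate.
#' @param roi_band,roi_stage Band (Hz) and stage whose significant cluster
#'   defines the ROI for the ANOVAs and correlations.
#' @param correlation_vars Clinical covariates correlated with ROI power.
#' @param correlation_group Group within which correlations are computed.
#' @param amplitude_threshold_uv,bad_channel_z,highpass_cutoff,bandpass
#'   Preprocessing parameters.
#' @param seed Master seed for the run.
#' @return An `analysis_config` (named list).
#' @export
analysis_config <- function(output_dir,
                            input_dir = NULL, synthetic = NULL,
                            bands = canonical_bands(),
                            stages = c("NREM", "N2", "N3", "R",
                                       "wake_presleep"),
                            n_permutations = 1000,
                            forming_alpha = 0.05, cluster_alpha = 0.05,
                            use_age_covariate = TRUE,
                            roi_band = c(3, 10), roi_stage = "N3",
                            correlation_vars = c("age", "tst_estimate",
                                                 "mslt_latency",
                                                 "conners_global",
                                                 "wisc_global"),
                            correlation_group = "affected",
                            amplitude_threshold_uv = 500,
                            bad_channel_z = 5,
                            highpass_cutoff = 0.1, bandpass = c(0.5, 45),
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Validate an analysis configuration
#'
#' Collects every structural problem instead of stopping at the first.
#'
#' @param config An `analysis_config`.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$input_dir) && is.null(config$synthetic)) {
    add("either input_dir or a synthetic cohort_spec is required")
  }
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      add(paste("input_dir does not exist:", config$input_dir))
    } else if (!file.exists(file.path(config$input_dir, "montage.csv"))) {
      add("input_dir is missing montage.csv")
    }
  }
  if (!is.null(config$synthetic) && !inherits(config$synthetic, "cohort_spec")) {
    add("synthetic must be a cohort_spec")
  }
  if (is.null(config$n_permutations) || config$n_permutations < 100) {
    add("n_permutations must be at least 100")
  }
  for (a in c("forming_alpha", "cluster_alpha")) {
    v <- config[[a]]
    if (is.null(v) || v <= 0 || v >= 1) add(paste(a, "must lie in (0, 1)"))
  }
  if (!all(config$stages %in% c("W", "N1", "N2", "N3", "R", "NREM",
                                "wake_presleep"))) {
    add("unknown stage in stages")
  }
  if (nrow(config$bands) == 0 || any(config$bands$hi <= config$bands$lo)) {
    add("bands must have hi > lo")
  }
  if (length(config$roi_band) != 2 || config$roi_band[2] <= config$roi_band[1]) {
    add("roi_band must be an increasing interval")
  }
  if (length(config$bandpass) != 2 || config$bandpass[2] <= config$bandpass[1]) {
    add("bandpass must be an increasing interval")
  }
  errs
}

#' Run the full power-topography analysis
#'
#' Executes the whole pipeline: cohort loading (or synthesis), per-subject
#' signal conditioning (high-pass, zero-phase band-pass, artifact masking,
#' bad-channel interpolation, average reference), stage-wise Welch spectra
#' and band maps (absolute and z-scored), cluster-corrected group
#' topographic statistics per band and stage (optionally with age covariate), the
#' whole-scalp spectrum test, ROI harvest from the configured band/stage
#' cluster, group x stage and group x cycle mixed ANOVAs on ROI power, and
#' clinical correlations. All tables are written under `output_dir`
#' together with a manifest recording the seed, configuration hash and
#' package version. Deterministic given the config (including its seed).
#'
#' @param config An `analysis_config`.
#' @return A `sleeptopo_report`: list of result tables (invisible copies of
#'   everything written to disk).
#' @export
run_full_analysis <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$output_dir, "INCOMPLETE")
  file.create(marker)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- step("load", {
    if (!is.null(config$synthetic)) simulate_cohort(config$synthetic)
    else read_fixtures(config$input_dir)
  })
  montage <- cohort$montage
  graph <- electrode_adjacency(montage)
  st <- cohort$subject_table

  # ---- per-subject conditioning and spectra (one subject in memory at a
  # time: signals are released as soon as the maps are extracted) ----
  maps <- list()
  spectra <- list()
  cycle_maps <- list()
  wake_excluded <- character()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    cohort$subjects[i] <- list(NULL)
    prep <- step("preprocess", {
      rec <- highpass_first_order(s$recording, config$highpass_cutoff)
      s$recording <- NULL
      rec <- bandpass_fir_zero_phase(rec, config$bandpass)
      mask <- mark_bad_segments(rec, config$amplitude_threshold_uv)
      bad <- detect_bad_channels(rec, config$bad_channel_z, graph)
      if (length(bad) > 0 && length(bad) < nrow(montage) / 4) {
        rec <- spherical_spline_interpolate(rec, bad)
      }
      list(rec = average_reference(rec), mask = mask)
    })
    rec <- prep$rec
    mask <- prep$mask
    prep <- NULL
    hyp <- s$hypnogram
    step("spectra", {
      for (stage in config$stages) {
        es <- if (stage == "wake_presleep") {
          w <- select_presleep_wake(rec, hyp, mask)
          if (w$excluded) {
            wake_excluded <- c(wake_excluded, s$subject_id)
            next
          }
          w$epochs
        } else {
          extract_stage_epochs(rec, hyp, stage, mask)
        }
        if (n_epochs(es) == 0) next
        psd <- welch_psd(es)
        maps[[length(maps) + 1]] <- band_power(psd, config$bands)
        if (stage %in% unique(c(config$roi_stage, "N2", "N3"))) {
          bins <- one_hz_bins(psd)
          bins$band <- paste0("bin_", bins$band)
          maps[[length(maps) + 1]] <- bins
        }
        if (stage == config$roi_stage) {
          spectra[[length(spectra) + 1]] <- channel_average_spectrum(psd)
        }
      }
      cyc <- detect_sleep_cycles(hyp)
      if (nrow(cyc) > 0) {
        roi_bands <- tibble::tibble(band = "roi_band",
                                    lo = config$roi_band[1],
                                    hi = config$roi_band[2])
        cm <- per_cycle_power(rec, hyp, cyc, config$roi_stage,
                              roi_bands, mask)
        if (nrow(cm) > 0) cycle_maps[[length(cycle_maps) + 1]] <- cm
      }
    })
    rm(rec, s)
  }
  maps <- dplyr::bind_rows(maps)
  spectra <- dplyr::bind_rows(spectra)
  cycle_maps <- dplyr::bind_rows(cycle_maps)

  # ---- cluster tests per band x stage x normalization ----
  roi_bands_tbl <- tibble::tibble(band = "roi_band", lo = config$roi_band[1],
                                  hi = config$roi_band[2])
  tests <- list()
  step("topocluster", {
    grid <- dplyr::distinct(maps[!startsWith(maps$band, "bin_"),
                                 c("stage", "band")])
    covs <- if (isTRUE(config$use_age_covariate)) list(NULL, "age")
            else list(NULL)
    for (i in seq_len(nrow(grid))) {
      for (norm in c("absolute", "zscore")) {
        m <- dplyr::filter(maps, stage == grid$stage[i],
                           band == grid$band[i])
        if (length(unique(m$subject)) < 4) next
        if (norm == "zscore") m <- zscore_channels(m)
        for (cov in covs) {
          key <- paste(grid$stage[i], grid$band[i], norm,
                       if (is.null(cov)) "plain" else cov, sep = ".")
          tests[[key]] <- cluster_permutation_test(
            m, st, graph, n_permutations = config$n_permutations,
            forming_alpha = config$forming_alpha,
            cluster_alpha = config$cluster_alpha,
            covariate = cov, seed = config$seed)
        }
      }
    }
  })

  spectrum_test <- NULL
  if (nrow(spectra) > 0 && length(unique(spectra$subject)) >= 4) {
    spectrum_test <- step("spectrum", spectrum_cluster_test(
      spectra, st, n_permutations = config$n_permutations,
      forming_alpha = config$forming_alpha,
      cluster_alpha = config$cluster_alpha, seed = config$seed))
  }

  # ---- ROI harvest: cluster surviving correction in roi_band at roi_stage ----
  roi_result <- step("roi", {
    m <- dplyr::filter(maps, stage == config$roi_stage,
                       startsWith(band, "bin_"))
    roi_map <- NULL
    if (nrow(m) > 0) {
      bin_f <- as.numeric(sub("bin_", "", m$band))
      m2 <- m[bin_f >= config$roi_band[1] & bin_f < config$roi_band[2], ]
      roi_map <- dplyr::summarise(
        dplyr::group_by(m2, subject, channel), value = mean(value),
        .groups = "drop")
    }
    if (is.null(roi_map) || length(unique(roi_map$subject)) < 4) NULL
    else cluster_permutation_test(
      roi_map, st, graph, n_permutations = config$n_permutations,
      forming_alpha = config$forming_alpha,
      cluster_alpha = config$cluster_alpha, seed = config$seed)
  })
  roi <- if (!is.null(roi_result)) significant_channels(roi_result,
                                                        "positive")
         else character()

  # ---- ROI ANOVAs and correlations ----
  inference <- list(stage_anova = NULL, cycle_anova = NULL,
                    correlations = NULL)
  if (length(roi) > 0) {
    inference <- step("roi_inference", {
      stage_anova <- cycle_anova <- correlations <- roi_power <- NULL
      # ROI endpoint per stage from the roi_band frequency range
      ep <- dplyr::filter(maps, stage %in% c("N2", "N3"),
                          startsWith(band, "bin_"))
      if (nrow(ep) > 0) {
        bin_f <- as.numeric(sub("bin_", "", ep$band))
        ep <- ep[bin_f >= config$roi_band[1] & bin_f < config$roi_band[2], ]
        ep <- dplyr::summarise(dplyr::group_by(ep, subject, stage, channel),
                               value = mean(value), .groups = "drop")
        ep <- roi_mean(ep, intersect(roi, unique(ep$channel)))
        ep <- dplyr::left_join(ep, st[, c("subject", "group")],
                               by = "subject")
        if (length(unique(ep$stage)) == 2) {
          stage_anova <- mixed_anova(ep, "value", "subject", "stage",
                                     "group")
        }
      }
      if (nrow(cycle_maps) > 0) {
        cp <- roi_mean(cycle_maps, intersect(roi, unique(cycle_maps$channel)))
        cp <- dplyr::left_join(cp, st[, c("subject", "group")],
                               by = "subject")
        if (length(unique(cp$cycle)) >= 2) {
          cycle_anova <- mixed_anova(cp, "value", "subject", "cycle",
                                     "group")
        }
        roi_power <- cp
      }
      grp_tbl <- dplyr::filter(st, group == config$correlation_group)
      if (!is.null(roi_power)) {
        c1 <- dplyr::filter(roi_power, cycle == min(roi_power$cycle),
                            subject %in% grp_tbl$subject)
        dat <- dplyr::left_join(grp_tbl, c1[, c("subject", "value")],
                                by = "subject")
        dat <- dat[!is.na(dat$value), ]
        vars <- intersect(config$correlation_vars, names(dat))
        if (nrow(dat) >= 5 && length(vars) > 0) {
          correlations <- correlate_clinical(dat, "value", vars,
                                             partial_on = "age")
        }
      }
      list(stage_anova = stage_anova, cycle_anova = cycle_anova,
           correlations = correlations)
    })
  }

  report <- structure(list(
    config = config, subject_table = st, maps = maps, spectra = spectra,
    cycle_maps = cycle_maps, tests = tests, spectrum_test = spectrum_test,
    roi_result = roi_result, roi = roi,
    stage_anova = inference$stage_anova,
    cycle_anova = inference$cycle_anova,
    correlations = inference$correlations,
    wake_excluded = unique(wake_excluded)
  ), class = "sleeptopo_report")

  step("write", write_report(report, config$output_dir))
  file.remove(marker)
  invisible(report)
}

# serialize the report tables under the output directory with a manifest
write_report <- function(report, dir) {
  config <- report$config
  written <- character()
  wtsv <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(d), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <<- c(written, p)
  }
  wjson <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, pretty = TRUE, auto_unbox = TRUE,
                         digits = 10, force = TRUE)
    written <<- c(written, p)
  }
  wtsv(report$maps, "power_maps.tsv")
  if (nrow(report$spectra)) wtsv(report$spectra, "spectra.tsv")
  if (nrow(report$cycle_maps)) wtsv(report$cycle_maps, "cycle_maps.tsv")
  cl <- lapply(report$tests, function(t) {
    list(clusters = t$clusters, critical = t$critical,
         n_permutations = t$n_permutations, seed = t$seed,
         null_mode = t$null_mode)
  })
  wjson(cl, "cluster_tests.json")
  if (!is.null(report$spectrum_test)) {
    wjson(report$spectrum_test$ranges, "spectrum_ranges.json")
  }
  wjson(list(roi = report$roi), "roi.json")
  if (!is.null(report$stage_anova)) {
    wjson(list(table = tidy(report$stage_anova),
               pairwise = report$stage_anova$pairwise),
          "anova_group_by_stage.json")
  }
  if (!is.null(report$cycle_anova)) {
    wjson(list(table = tidy(report$cycle_anova),
               pairwise = report$cycle_anova$pairwise),
          "anova_group_by_cycle.json")
  }
  if (!is.null(report$correlations)) {
    wtsv(report$correlations, "correlations.tsv")
  }
  cfg <- config
  cfg$synthetic <- if (is.null(cfg$synthetic)) NULL else unclass(cfg$synthetic)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sleeptopo")),
    seed = config$seed,
    config_hash = rlang::hash(cfg),
    wake_excluded = report$wake_excluded,
    files = basename(written)
  )
  wjson(manifest, "run_manifest.json")
  invisible(written)
}

#' @export
print.sleeptopo_report <- function(x, ...) {
  cat("sleeptopo analysis report:", length(unique(x$maps$subject)),
      "subjects,", length(x$tests), "cluster tests\n")
  if (length(x$roi)) {
    cat("ROI (", length(x$roi), " channels):",
        paste(utils::head(x$roi, 8), collapse = " "),
        if (length(x$roi) > 8) "..." else "", "\n")
  } else cat("ROI: none survived correction\n")
  invisible(x)
}
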