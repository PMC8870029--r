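#' Plot a power topography
#'
#' Quick-control scalp map: channels at their 2-D azimuthal projection,
#' coloured by value. For multi-band maps, facets per band.
#'
#' @param map Tidy power map with columns `channel`, `value` (optionally
#'   `band`); values are averaged over subjects if several are present.
#' @param montage The `eeg_montage` providing channel positions.
#' @return A ggplot object.
#' @export
plot_topography <- function(map, montage) {
  validate_montage(montage)
  proj <- azimuthal_projection(montage_positions(montage))
  coords <- tibble::tibble(channel = montage$channel,
                           px = proj[, 1], py = proj[, 2])
  grp <- dplyr::group_by(map, dplyr::across(dplyr::any_of(c("channel", "band"))))
  d <- dplyr::ungroup(dplyr::summarise(grp, value = mean(value),
                                       .groups = "drop"))
  d <- dplyr::left_join(d, coords, by = "channel")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = px, y = py, colour = value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "power")
  if ("band" %in% names(d)) p <- p + ggplot2::facet_wrap(~band)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cluster permutation result
#'
#' Scalp map of the per-channel t statistic with channels of significant
#' clusters circled.
#'
#' @param object A `cluster_result` (with channel labels matching `montage`).
#' @param montage The `eeg_montage`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, montage, ...) {
  validate_montage(montage)
  proj <- azimuthal_projection(montage_positions(montage))
  d <- object$channel_stats
  d$px <- proj[match(d$channel, montage$channel), 1]
  d$py <- proj[match(d$channel, montage$channel), 2]
  d$in_cluster <- d$channel %in% significant_channels(object)
  ggplot2::ggplot(d, ggplot2::aes(x = px, y = py)) +
    ggplot2::geom_point(ggplot2::aes(colour = t), size = 3) +
    ggplot2::geom_point(data = d[d$in_cluster, ], shape = 1, size = 5,
                        stroke = 1) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "t")
}

#' Plot group spectra with significant ranges
#'
#' Group-mean channel-averaged spectra on a log scale, shading the
#' frequency ranges flagged by [spectrum_cluster_test()].
#'
#' @param spectra Tidy spectra (`subject`, `freq`, `value`).
#' @param subject_table Table with `subject`, `group`.
#' @param result Optional `cluster_result` from [spectrum_cluster_test()].
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, subject_table, result = NULL) {
  d <- dplyr::left_join(tibble::as_tibble(spectra),
                        subject_table[, c("subject", "group")],
                        by = "subject")
  g <- dplyr::summarise(dplyr::group_by(d, group, freq),
                        value = mean(value), .groups = "drop")
  p <- ggplot2::ggplot(g, ggplot2::aes(freq, value, colour = group)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD~(mu*V^2/Hz))) +
    ggplot2::theme_minimal()
  if (!is.null(result) && nrow(result$ranges) > 0) {
    rg <- result$ranges[result$ranges$significant, , drop = FALSE]
    if (nrow(rg)) {
      ylim <- range(g$value)                  # finite bounds: log-scale safe
      p <- p + ggplot2::geom_rect(
        data = as.data.frame(rg), inherit.aes = FALSE,
        ggplot2::aes(xmin = lo - 0.5, xmax = hi + 0.5),
        ymin = log10(ylim[1] / 2), ymax = log10(ylim[2] * 2),
        alpha = 0.15)
    }
  }
  p
}
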