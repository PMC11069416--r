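#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a wavelet coherence spectrogram
#'
#' Time-frequency raster of squared coherence with the cone-of-influence
#' boundary overlaid (estimates below the line are edge-affected) and the
#' three analysis bands marked.
#'
#' @param object A `"coherence_spectrogram"` from [wtc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coherence_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$r2 <- as.vector(object$r2)
  coi_df <- tibble::tibble(time = object$times,
                           coi = pmin(object$coi, max(object$freqs)))
  bands <- frequency_bands()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$r2)) +
    ggplot2::geom_line(data = coi_df,
                       ggplot2::aes(x = .data$time, y = .data$coi),
                       linetype = "dashed", colour = "white") +
    ggplot2::geom_hline(yintercept = unique(c(bands$lo_hz, bands$hi_hz)),
                        colour = "grey80", linewidth = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(r^2)) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = "Wavelet transform coherence")
}

#' Plot a permutation grid
#'
#' ROI-by-band tile plot of the observed real-minus-pseudo differences with
#' the permutation p-values printed in each cell.
#'
#' @param object A `"permutation_grid"` from [permutation_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$band)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$observed_diff)) +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$p), "-", sprintf("p=%.3f", .data$p))),
      size = 3) +
    ggplot2::scale_fill_gradient2(name = "real - pseudo") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Permutation grid: %s", df$measure[1]))
}

#' Plot band coherence values by group
#'
#' Box plots of per-dyad band coherence, split by real/pseudo group, one
#' panel per band, for a chosen trial or measure column.
#'
#' @param band_values Tidy values from [cohort_band_coherence()] (uses
#'   `value`) or [coherence_measures()] (pick a `measure` column).
#' @param measure Column to plot; default `"value"`.
#' @return A ggplot object.
#' @export
plot_band_coherence <- function(band_values, measure = "value") {
  if (!measure %in% names(band_values))
    abort(sprintf("column '%s' absent", measure))
  df <- band_values
  df$group <- ifelse(df$is_real, "real", "pseudo")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data[[measure]],
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
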