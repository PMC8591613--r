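# autoplot() methods for the main result types.

#' @method autoplot opm_virtual_channel
#' @export
autoplot.opm_virtual_channel <- function(object, ...) {
  df <- object$t
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$t)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Time from stimulus onset (s)", y = "t value",
                  title = "ROI virtual channel (pointwise one-sample t)") +
    ggplot2::theme_minimal()
}

#' @method autoplot opm_source_map
#' @export
autoplot.opm_source_map <- function(object, slice = c("y", "max"), ...) {
  df <- as_tibble(object)
  # collapse over the down-up axis: maximum-intensity projection
  proj <- df |>
    group_by(.data$x, .data$z) |>
    summarise(nai = max(.data$nai), .groups = "drop")
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$nai)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x, right-left (m)", y = "z, back-forward (m)",
                  fill = "NAI",
                  title = "NAI map (axial maximum-intensity projection)") +
    ggplot2::theme_minimal()
}

#' @method autoplot kinematics_summary
#' @export
autoplot.kinematics_summary <- function(object, ...) {
  ggplot2::ggplot(object$histograms,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~dof, scales = "free") +
    ggplot2::labs(x = NULL, y = "frames",
                  title = "Rigid-body degree-of-freedom histograms") +
    ggplot2::theme_minimal()
}

#' @method autoplot opm_evoked
#' @export
autoplot.opm_evoked <- function(object, channels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$field * 1e15,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey70") +
    ggplot2::labs(x = "Time from stimulus onset (s)", y = "Field (fT)",
                  title = "Sensor-level evoked response") +
    ggplot2::theme_minimal()
}

#' Plot the PSD triptych of a condition result
#'
#' Raw sensor, preprocessed sensor and source-level ROI power spectral
#' densities on one dB scale, restricted to `band`.
#'
#' @param result an `opm_condition_result`.
#' @param band frequency band to display, Hz.
#' @return A ggplot object.
#' @export
plot_psd_triptych <- function(result, band = c(2, 10)) {
  df <- purrr::imap(result$psds, function(p, nm) mutate(p, series = nm)) |>
    bind_rows() |>
    filter(.data$freq >= band[1], .data$freq <= band[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq,
                                   y = 10 * log10(.data$power),
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (dB)",
                  title = sprintf("PSD, preset '%s'", result$preset)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the stage-wise field-change table
#'
#' Mean per-trial maximal field change after each pre-processing stage, in
#' picoTesla on a log scale.
#'
#' @param result an `opm_condition_result`.
#' @return A ggplot object.
#' @export
plot_stage_table <- function(result) {
  df <- result$stage_table |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage,
                                   y = .data$field_change * 1e12)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Mean per-trial max field change (pT)",
                  title = sprintf("Interference suppression, preset '%s'",
                                  result$preset)) +
    ggplot2::theme_minimal()
}
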