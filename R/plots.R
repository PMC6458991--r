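#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_abline facet_wrap labs scale_fill_gradient2 theme_minimal
#'   stat_summary position_dodge
NULL

#' Plot a time-frequency percent-change matrix
#'
#' @param object An `nvc_tfr` from [percent_change_tfr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nvc_tfr <- function(object, ...) {
  d <- tidyr::expand_grid(
    time_s = (seq_len(nrow(object$values)) - 1) / object$rate,
    freq_hz = object$freq)
  d$pct <- as.vector(t(object$values))
  ggplot(d, aes(.data$time_s, .data$freq_hz, fill = .data$pct)) +
    geom_raster() +
    scale_fill_gradient2(name = "% change") +
    labs(x = "Time (s)", y = "Frequency (Hz)",
         title = "Gamma power change from rest baseline") +
    theme_minimal()
}

#' Plot a per-subject coupling fit
#'
#' @param object A `coupling_fit` from [fit_coupling()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coupling_fit <- function(object, ...) {
  d <- tibble::tibble(gamma = object$model$model$x,
                      response = object$model$model$y)
  ggplot(d, aes(.data$gamma, .data$response)) +
    geom_point() +
    geom_abline(slope = object$gradient, intercept = object$intercept) +
    labs(x = "Peak gamma change (%)", y = object$measure,
         title = sprintf("Coupling fit (gradient %.3g)", object$gradient)) +
    theme_minimal()
}

#' Plot a gamma power-change map (axial slice through the peak)
#'
#' @param object A `gamma_power_map` from [scan_percent_change()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gamma_power_map <- function(object, ...) {
  zs <- object$peak_loc[3]
  sl <- dplyr::filter(object$map, abs(.data$z - zs) < object$grid$spacing / 2,
                      .data$inside)
  ggplot(sl, aes(.data$x, .data$y, fill = .data$pct)) +
    geom_raster() +
    geom_point(aes(x = object$peak_loc[1], y = object$peak_loc[2]),
               inherit.aes = FALSE, shape = 4, size = 3) +
    scale_fill_gradient2(name = "% change") +
    labs(x = "x (m)", y = "y (m)",
         title = sprintf("Gamma power change, axial slice z = %.3f m", zs)) +
    theme_minimal()
}

#' Cohort mean responses by contrast and group
#'
#' Mean with standard-error bars of the per-subject (eye-averaged) measures
#' across contrast levels, faceted by measure.
#'
#' @param measures Cohort measures tibble.
#' @param cols Measure columns to include.
#' @return A ggplot.
#' @export
plot_cohort_responses <- function(measures,
                                  cols = c("gamma_pct", "bold_pct",
                                           "cbf_pct", "cbf_abs")) {
  d <- measures |>
    dplyr::group_by(.data$subject, .data$group, .data$contrast) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "measure")
  ggplot(d, aes(factor(.data$contrast * 100), .data$value,
                color = .data$group, group = .data$group)) +
    stat_summary(fun = mean, geom = "line",
                 position = position_dodge(0.2)) +
    stat_summary(fun.data = ggplot2::mean_se, geom = "pointrange",
                 position = position_dodge(0.2)) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "Michelson contrast (%)", y = "Response",
         color = "Group") +
    theme_minimal()
}
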