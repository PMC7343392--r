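# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coherence profile
#'
#' MSC against frequency, optionally with the band of maximum coherence
#' shaded and the conventional high-frequency HRV band (0.15-0.4 Hz)
#' marked.
#'
#' @param object A `coh_profile` tibble.
#' @param band Optional `max_coh_band` (or `c(lower, upper)` Hz) to shade.
#' @param hf_band Show the 0.15-0.4 Hz HF-HRV reference band.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coh_profile
#' @export
autoplot.coh_profile <- function(object, band = NULL, hf_band = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$msc)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude-squared coherence") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (hf_band) {
    p <- p + ggplot2::annotate("rect", xmin = 0.15, xmax = 0.4,
                               ymin = -Inf, ymax = Inf, alpha = 0.08,
                               fill = "grey40")
  }
  if (!is.null(band)) {
    rng <- if (inherits(band, "max_coh_band")) c(band$lower, band$upper) else band
    p <- p + ggplot2::annotate("rect", xmin = rng[1], xmax = rng[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "#c0392b")
  }
  p
}

#' Plot a repeated-measures correlation
#'
#' Observations colored by subject with the common-slope fit overlaid per
#' subject (parallel lines shifted by the subject intercepts).
#'
#' @param object An `lc_rmcorr`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lc_rmcorr
#' @export
autoplot.lc_rmcorr <- function(object, ...) {
  d <- object$data
  fit <- lm(y ~ subject + x, data = dplyr::mutate(d, subject = factor(.data$subject)))
  d$fitted <- stats::fitted(fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$subject)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::guides(color = "none") +
    ggplot2::labs(
      title = sprintf("r_rm(%d) = %.3f, p = %.3g", object$df, object$r,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot stage measures across the task
#'
#' Violin-and-point display of one stage measure (rMSSD, delta-sAA, LC
#' variance or band-median coherence) across task stages.
#'
#' @param measures The `stage_measures` tibble from [run_all()].
#' @param measure Column to plot.
#' @return A ggplot.
#' @export
plot_stage_measures <- function(measures, measure = "delta_saa") {
  d <- measures[!is.na(measures[[measure]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$stage,
                                             levels = unique(.data$stage)),
                                  y = .data[[measure]])) +
    ggplot2::geom_violin(fill = "#aac7e2", alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Task stage", y = measure) +
    ggplot2::theme_minimal()
}
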