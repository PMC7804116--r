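# ggplot2 views of the main result types

#' Fold-change landscape plot
#'
#' Tile plot of the model fold change (or either expression surface) over
#' the proximal/distal operator energy grid.
#'
#' @param grid Tibble from [expression_grid()].
#' @param surface Which surface to draw: `"fold_change"`, `"uninduced"` or
#'   `"induced"`.
#' @return A ggplot object.
#' @export
plot_landscape <- function(grid, surface = c("fold_change", "uninduced", "induced")) {
  surface <- match.arg(surface)
  ggplot2::ggplot(grid, ggplot2::aes(.data$e_prox, .data$e_dist)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data[[surface]]))) +
    ggplot2::scale_fill_viridis_c(name = paste0("log10 ", surface)) +
    ggplot2::labs(
      x = "proximal operator energy (kT)",
      y = "distal operator energy (kT)"
    ) +
    ggplot2::theme_minimal()
}

#' Operator-spacing profile plot
#'
#' Relative expression against distal-site position with the loess smooth
#' and shaded in-phase windows (helical period 10.5 bp).
#'
#' @param profile Tibble with `position` and `value` (e.g. relative
#'   expression); a `smoothed` column from [loess_profile()] is drawn when
#'   present.
#' @param proximal_center,period Passed to [phase_annotation()].
#' @return A ggplot object.
#' @export
plot_spacing_profile <- function(profile, proximal_center = 12L, period = 10.5) {
  phases <- phase_annotation(profile$position, proximal_center, period)
  shade <- phases[phases$in_phase, ]
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$position, .data$value))
  if (nrow(shade) > 0L) {
    p <- p + ggplot2::geom_vline(
      xintercept = shade$position, colour = "grey85", linewidth = 2
    )
  }
  p <- p + ggplot2::geom_line(colour = "grey50") + ggplot2::geom_point()
  if ("smoothed" %in% names(profile)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$smoothed), colour = "#2166AC", linewidth = 1
    )
  }
  p + ggplot2::labs(
    x = "distal site centre (position relative to TSS)",
    y = "relative expression"
  ) + ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot for a fitted model
#'
#' @param object A `promoter_fit`.
#' @param ... Unused.
#' @return A ggplot object of observed against model-predicted expression
#'   on log10 axes, coloured by condition.
#' @exportS3Method ggplot2::autoplot
autoplot.promoter_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$residuals,
    ggplot2::aes(.data$predicted, .data$observed, colour = .data$condition)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "model-predicted expression",
      y = "measured expression"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
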