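#' Architecture diagram of annotated sequences
#'
#' Draws each sequence as a horizontal track with motif annotations
#' coloured by class and, optionally, spacer and tandem-repeat intervals
#' as outlined boxes -- a text-free rendition of the classic spidroin
#' architecture cartoon.
#'
#' @param motifs Output of [scan_motifs()].
#' @param spacers Optional output of [detect_spacers()].
#' @param repeats Optional output of [find_tandem_repeats()].
#' @return A ggplot object.
#' @export
plot_architecture <- function(motifs, spacers = NULL, repeats = NULL) {
  p <- ggplot2::ggplot(motifs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$id,
                   yend = .data$id, colour = .data$motif_class),
      linewidth = 4) +
    ggplot2::labs(x = "position (aa)", y = NULL, colour = "motif") +
    ggplot2::theme_minimal()
  if (!is.null(repeats) && nrow(repeats)) {
    p <- p + ggplot2::geom_rect(
      data = repeats,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = as.numeric(factor(.data$id)) - 0.35,
                   ymax = as.numeric(factor(.data$id)) + 0.35),
      inherit.aes = FALSE, fill = NA, colour = "grey40",
      linetype = "dashed")
  }
  if (!is.null(spacers) && nrow(spacers)) {
    p <- p + ggplot2::geom_segment(
      data = spacers,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$id,
                   yend = .data$id),
      inherit.aes = FALSE, linewidth = 6, colour = "black", alpha = 0.35)
  }
  p
}

#' Hydropathy profile plot
#'
#' @param profile Output of [hydropathy_profile()].
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$id), ncol = 1) +
    ggplot2::labs(x = "position (aa)", y = "Kyte-Doolittle score") +
    ggplot2::theme_minimal()
}

#' @describeIn tensile_trace True stress-strain plot of a trace.
#' @param object A `tensile_trace`.
#' @param ... Unused.
#' @export
autoplot.tensile_trace <- function(object, ...) {
  curve <- true_curve(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$true_strain,
                                      y = .data$true_stress_MPa)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "true strain (ln mm/mm)", y = "true stress (MPa)") +
    ggplot2::theme_minimal()
}

#' @describeIn silk_regress Scatter plot with the fitted line.
#' @param object A `silk_regression`.
#' @export
autoplot.silk_regression <- function(object, ...) {
  intercept <- if (object$through_origin) 0 else object$intercept
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      subtitle = sprintf("adj. R² = %.2f, p = %.3g, n = %d",
                         object$adjusted_r_squared, object$p_value,
                         object$n)) +
    ggplot2::theme_minimal()
}
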