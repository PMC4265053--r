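# ggplot2 visualizations for each result type.

#' Plot a designed RBS library against its coverage grid
#'
#' Predicted per-variant translation rates (rank-ordered, log scale) with the
#' bin-grid fill windows shaded, mirroring how optimized libraries are
#' assessed against their targeted rate space.
#'
#' @param object An [optimize_rbs_library()] result.
#' @param rank Solution rank to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rbs_library_design <- function(object, rank = 1L, ...) {
  vr <- object$variant_rates[object$variant_rates$rank == rank, ]
  vr <- dplyr::arrange(vr, .data$rate_au)
  vr$index <- seq_len(nrow(vr))
  grid <- object$grid
  bins <- tibble::tibble(center = grid$centers,
                         lo = grid$centers / 10^grid$W,
                         hi = grid$centers * 10^grid$W)
  ggplot2::ggplot(vr, ggplot2::aes(x = .data$index, y = .data$rate_au)) +
    ggplot2::geom_hline(data = bins, ggplot2::aes(yintercept = .data$center),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(colour = "#b2182b", size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "variant (rank-ordered)",
                  y = "predicted translation initiation rate (au)",
                  title = sprintf("degenerate RBS %s: C = %.2f, N = %d",
                                  object$solutions$degenerate_rbs[rank],
                                  object$solutions$coverage[rank],
                                  as.integer(object$solutions$n_variants[rank])))
}

#' Plot per-generation best objective of a design run
#'
#' @param design An [optimize_rbs_library()] result.
#' @return A ggplot.
#' @export
plot_design_history <- function(design) {
  ggplot2::ggplot(design$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_objective)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best objective F")
}

#' Plot predicted vs measured productivities of a fit
#'
#' @param object An [identify_parameters()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seamap_fit <- function(object, ...) {
  aug <- augment.seamap_fit(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$measured, y = .data$predicted,
                                    colour = .data$is_reference)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "measured productivity (ug/gDCW/h)",
                  y = "predicted productivity (ug/gDCW/h)")
}

#' Plot a transcription-induction response curve
#'
#' @param object A [response_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$transcription_multiplier,
                                       y = .data$productivity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "transcription-rate multiplier",
                  y = "predicted productivity (ug/gDCW/h)")
}

#' Histogram of an evolutionary landscape
#'
#' @param object An [evolutionary_landscape()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evolutionary_landscape <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = log2(.data$productivity_ratio))) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, colour = "#b2182b") +
    ggplot2::labs(x = "log2 productivity change",
                  y = "mutant count",
                  title = sprintf("%d random RBS mutation(s): %.0f%% decrease productivity",
                                  object$n_mutations,
                                  100 * object$fraction_decreased))
}
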