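#' Plot an accuracy report as a fetal-fraction by read-depth heatmap
#'
#' One tile per grid cell (accuracy averaged over fetal conditions),
#' faceted by model configuration and chromosome-level method.
#'
#' @param object A `nipt_accuracy_report` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nipt_accuracy_report <- function(object, ...) {
  df <- object$cells |>
    dplyr::group_by(.data$model, .data$method, .data$ff, .data$rd) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(factor(100 * .data$ff),
                                   factor(.data$rd),
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(model ~ method) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "ACC") +
    ggplot2::labs(x = "fetal fraction (%)", y = "read depth") +
    ggplot2::theme_minimal()
}

#' Plot decoded locus states along a chromosome
#'
#' @param decoded A [decode_sample()] result.
#' @return A ggplot object.
#' @export
plot_locus_states <- function(decoded) {
  y <- if ("total" %in% names(decoded)) "total" else "ratio"
  ggplot2::ggplot(decoded, ggplot2::aes(.data$locus, .data[[y]],
                                        colour = .data$condition_call)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "locus", y = y, colour = "decoded condition") +
    ggplot2::theme_minimal()
}

#' Plot the MAF-dependent informative-variant proportions
#'
#' Simulated means (points) against the closed-form theoretical curve
#' (line), per fetal condition.
#'
#' @param object A [maf_informative_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nipt_maf_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$maf, colour = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theoretical)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$simulated), shape = 1) +
    ggplot2::labs(x = "minor-allele frequency",
                  y = "proportion of informative SNPs") +
    ggplot2::theme_minimal()
}

#' Plot an experimental read-count call
#'
#' Decoded per-locus states of the studied chromosome in positional order.
#'
#' @param object A [call_experimental_sample()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nipt_experimental_call <- function(object, ...) {
  ggplot2::ggplot(object$loci,
                  ggplot2::aes(.data$position, .data$molecule_count,
                               colour = .data$state)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(EUP = "#2e7d32",
                                            TRI = "#c62828")) +
    ggplot2::labs(title = sprintf("%s: %s", object$call$sample_id,
                                  object$call$call),
                  x = "position", y = "molecule count") +
    ggplot2::theme_minimal()
}
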