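#' Plot a run chart
#'
#' Line-and-point chart of the series with the (fixed, baseline-derived)
#' median as a horizontal reference line; points on the median are hollow,
#' and the end of the baseline segment is marked when it is shorter than
#' the series.
#'
#' @param object A [run_chart()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot run_chart
#' @export
autoplot.run_chart <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$obs, y = .data$value)) +
    ggplot2::geom_hline(yintercept = object$median,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$position == "on"),
                        show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "Observation", y = "Value") +
    ggplot2::theme_minimal()
  if (object$baseline_len < nrow(d)) {
    p <- p + ggplot2::geom_vline(xintercept = object$baseline_len + 0.5,
                                 linetype = "dotted", colour = "grey60")
  }
  p
}

#' @rdname autoplot.run_chart
#' @param x A [run_chart()].
#' @param y Ignored.
#' @export
plot.run_chart <- function(x, y, ...) print(autoplot(x, ...))

#' Bar chart of likelihood ratios across the simulation grid
#'
#' One panel per condition (baseline:post-baseline lengths), bars for each
#' rule set's positive and negative likelihood ratio on a log scale, with
#' reference lines at the conventional strong-evidence thresholds 10 and
#' 0.1.
#'
#' @param sim A `rundx_sim` from [run_simulation_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_likelihood_ratios <- function(sim, ...) {
  stopifnot(inherits(sim, "rundx_sim"))
  d <- sim |>
    tibble::as_tibble() |>
    dplyr::select("condition", "rule_set", "lr_pos", "lr_neg") |>
    tidyr::pivot_longer(c("lr_pos", "lr_neg"),
                        names_to = "measure", values_to = "lr") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          lr_pos = "LR+", lr_neg = "LR-"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rule_set, y = .data$lr,
                                  fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(0.1, 1, 10),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "Likelihood ratio (log scale)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot rundx_sim
#' @export
autoplot.rundx_sim <- function(object, ...) plot_likelihood_ratios(object, ...)
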