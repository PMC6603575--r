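# ggplot2 views of the main result types.

#' Plot a delay sweep
#'
#' Delay versus average request rate: analytic curve, simulated points with
#' 95% intervals, and the periodic-only baseline mean for comparison.
#'
#' @param object A `delay_sweep` tibble from [delay_sweep()].
#' @param ... Unused.
#' @return A ggplot object (delays in milliseconds).
#' @method autoplot delay_sweep
#' @export
autoplot.delay_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ds_analytic * 1e3,
                                    colour = "analytic")) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$ds_sim * 1e3,
      ymin = (.data$ds_sim - .data$ci95) * 1e3,
      ymax = (.data$ds_sim + .data$ci95) * 1e3,
      colour = "simulated"), size = 0.3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline_mean[1] * 1e3,
                                     colour = "periodic baseline"),
                        linetype = "dashed") +
    ggplot2::labs(x = "average requests per frame",
                  y = "sensed-data delay [ms]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensor stream
#'
#' Axis accelerations and SMV over time, coloured by ground-truth label.
#'
#' @param stream A stream tibble from [generate_stream()].
#' @param max_points Thin the stream to at most this many samples.
#' @return A ggplot object.
#' @export
plot_stream <- function(stream, max_points = 5000) {
  if (nrow(stream) > max_points) {
    stream <- stream[seq(1, nrow(stream), length.out = max_points), ]
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(stream, smv = smv(.data$ax, .data$ay, .data$az)),
    c("ax", "ay", "az", "smv"), names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "acceleration [g]") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot heat map of the summed confusion matrix.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object$confusion)),
                          .name_repair = ~c("actual", "predicted", "n"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(activity_levels())) +
    ggplot2::scale_x_discrete(limits = activity_levels()) +
    ggplot2::labs(title = sprintf("%s, %d-fold CV, overall F = %.1f%%",
                                  object$spec$algorithm, object$k,
                                  object$report$overall_f)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
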