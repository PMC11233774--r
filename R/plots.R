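# ggplot2 displays for the result types.

#' Plot convergence curves
#'
#' Cumulative median absolute relative error and correlation against the
#' number of windows scored, one panel per statistic. A curve that flattens
#' as windows accumulate indicates the accuracy estimates have converged.
#'
#' @param curve Tibble from [convergence_curve()], optionally with `index`
#'   and `role` columns (as written by [run_evaluate()]) for facetting.
#' @return A ggplot object.
#' @export
plot_convergence <- function(curve) {
  long <- tidyr::pivot_longer(curve, c("err_median", "r"),
                              names_to = "statistic", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "windows scored", y = NULL) +
    ggplot2::theme_minimal()
  if ("index" %in% names(long)) {
    p <- p + ggplot2::facet_grid(
      stats::reformulate("statistic", "index"), scales = "free_y")
  } else {
    p <- p + ggplot2::facet_wrap(~statistic, scales = "free_y", ncol = 1)
  }
  p
}

#' Plot an accuracy report
#'
#' Median absolute relative error per index (bars) with the Pearson
#' correlation annotated, facetted by role when present.
#'
#' @param object An `"accuracy_report"` from [summarize_accuracy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  d$index <- factor(d$index, levels = rev(index_names))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$err_median, y = .data$index)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$r), "",
                                  sprintf("R = %.2f", .data$r))),
      hjust = -0.1, size = 2.8) +
    ggplot2::labs(x = "median absolute relative error (%)", y = NULL) +
    ggplot2::theme_minimal()
  if ("role" %in% names(d)) p <- p + ggplot2::facet_wrap(~role)
  p
}

#' Plot proximity intervals as a timeline
#'
#' @param intervals Tibble from [build_proximity_intervals()].
#' @return A ggplot object.
#' @export
plot_intervals <- function(intervals) {
  d <- dplyr::mutate(intervals, pair = paste(.data$id_a, .data$id_b, sep = " - "))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$pair)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$pair), linewidth = 3) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
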