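#' Plot a precision-recall curve
#'
#' Step curve of precision against recall with the class chance baseline
#' `P/(P+N)` as a dashed line.
#'
#' @param object A [pr_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dihm_pr_curve
#' @export
autoplot.dihm_pr_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = attr(object, "baseline"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = attr(object, "positive_class"),
      subtitle = sprintf("AP = %.3f, baseline = %.3f",
                         average_precision(object),
                         attr(object, "baseline")),
      x = "Recall", y = "Precision"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-class average precision against class baselines
#'
#' @param object A [metrics_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dihm_report
#' @export
autoplot.dihm_report <- function(object, ...) {
  df <- object$per_class
  df$class <- stats::reorder(df$class, df$average_precision)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$class)) +
    ggplot2::geom_col(ggplot2::aes(x = .data$average_precision),
                      fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$baseline), shape = 4) +
    ggplot2::labs(x = "Average precision (x = class baseline)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Display a reconstructed plane as a raster
#'
#' @param plane A `dihm_plane`.
#' @return A ggplot object.
#' @export
plot_plane <- function(plane) {
  stopifnot(inherits(plane, "dihm_plane"))
  amp <- plane$amplitude
  df <- tidyr::expand_grid(row = seq_len(nrow(amp)), col = seq_len(ncol(amp)))
  df$amplitude <- as.vector(amp)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %g um", plane$z)) +
    ggplot2::theme_void()
}
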