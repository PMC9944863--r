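# ggplot2 views of the main result types.

#' Boxplots of estimated mutual information by method
#'
#' @param object A `relcol_summary` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.relcol_summary <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$I))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$I)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.55) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::labs(x = NULL, y = "Estimated mutual information (bits)") +
    ggplot2::theme_minimal()
}

#' Mutual information against log2 of the number of relevant colors
#'
#' @param object A `relcol_regression` from [regression_mi_vs_logn()].
#' @param ... Unused.
#' @return A ggplot with the fitted line.
#' @export
autoplot.relcol_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$log2n, y = .data$I)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ "number of relevant colors"),
                  y = "Estimated mutual information (bits)") +
    ggplot2::theme_minimal()
}

#' Cluster-count index curve
#'
#' @param object A `relcol_nscan`.
#' @param ... Unused.
#' @return A ggplot of the index against n with the selected optimum marked.
#' @export
autoplot.relcol_nscan <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n, y = .data$index)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_opt, linetype = "dotted") +
    ggplot2::labs(x = "Number of clusters n", y = object$method) +
    ggplot2::theme_minimal()
}

#' Show a quantization's palette
#'
#' @param object A `relcol_quantization`.
#' @param ... Unused.
#' @return A ggplot of palette swatches sized by pixel share.
#' @export
autoplot.relcol_quantization <- function(object, ...) {
  d <- tidy(object)
  d$hex <- grDevices::rgb(clamp(d$R, 0, 255), clamp(d$G, 0, 255),
                          clamp(d$B, 0, 255), maxColorValue = 255)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$label), y = .data$fraction,
                                  fill = .data$hex)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = "Relevant color", y = "Pixel fraction") +
    ggplot2::theme_minimal()
}
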