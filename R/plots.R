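#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a work distribution
#'
#' Histogram of the work values with the normal density implied by the
#' sample mean and standard deviation overlaid, and vertical lines at the
#' Gaussian and Jarzynski free-energy estimates. A visibly skewed or
#' multimodal histogram with separated estimate lines is the picture
#' behind a convolution-branch decision.
#'
#' @param object A `work_set`.
#' @param bins Histogram bin count (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot work_set
#' @export
autoplot.work_set <- function(object, bins = 30, ...) {
  w <- unclass(object)
  df <- tibble::tibble(W = w)
  est <- tibble::tibble(
    estimate = c("gaussian", "jarzynski"),
    dG = c(if (length(w) > 1) dg_gaussian(object)$dG else NA_real_,
           dg_jarzynski(object)$dG))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$W)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey75", colour = "grey40") +
    ggplot2::geom_vline(data = est,
                        ggplot2::aes(xintercept = .data$dG,
                                     colour = .data$estimate),
                        linewidth = 0.7) +
    ggplot2::labs(x = "work (kcal/mol)", y = "density", colour = NULL,
                  title = attr(object, "label"))
  if (length(w) > 1 && stats::sd(w) > 0) {
    p <- p + ggplot2::stat_function(fun = stats::dnorm,
                                    args = list(mean = mean(w), sd = stats::sd(w)),
                                    linetype = 2)
  }
  p
}

#' Heatmap of a concordance matrix
#'
#' @param object A `ccc_matrix` from [ccc_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccc_matrix
#' @export
autoplot.ccc_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("row", "col", "ccc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ccc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ccc))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(min(object), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CCC")
}

#' Experimental-calculated parity plot
#'
#' Scatter of calculated against experimental values with the identity
#' line and the OLS best-fit line, the standard picture for benchmark
#' quality.
#'
#' @param data Data frame with the two columns.
#' @param exp_col,calc_col Column names (strings).
#' @param label_col Optional name column used to label points.
#' @return A ggplot object.
#' @export
plot_parity <- function(data, exp_col, calc_col, label_col = NULL) {
  stopifnot(all(c(exp_col, calc_col) %in% names(data)))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[exp_col]],
                                          y = .data[[calc_col]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0(exp_col, " (experimental)"),
                  y = paste0(calc_col, " (calculated)"))
  if (!is.null(label_col)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data[[label_col]]),
                                vjust = -0.7, size = 3)
  }
  p
}
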