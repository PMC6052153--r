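# ggplot2 views of the result types.

#' Plot a sliding-window divergence profile
#'
#' Divergence (percent) against window midpoint, one line per comparison,
#' with a horizontal rule at the species-delimitation threshold and a shaded
#' band between the per-window minimum and maximum pairwise values.
#'
#' @param object a `window_profile` from [sliding_window()].
#' @param threshold percent divergence rule to draw (default 3.5; `NA` to
#'   omit).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.window_profile <- function(object, threshold = 3.5, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$midpoint, y = 100 * .data$d, colour = .data$comparison,
    fill = .data$comparison)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$d_min,
                                      ymax = 100 * .data$d_max),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window midpoint (bp)",
                  y = "Jukes-Cantor divergence (%)",
                  colour = "comparison", fill = "comparison") +
    ggplot2::theme_minimal()
  if (!is.na(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @rdname autoplot.window_profile
#' @param profile a `window_profile`.
#' @export
plot_window_profile <- function(profile, threshold = 3.5, ...) {
  autoplot.window_profile(profile, threshold = threshold, ...)
}

#' Plot a divergence matrix as a heatmap
#'
#' @param object a `divergence_matrix` (percent).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_matrix <- function(object, ...) {
  df <- tidy.divergence_matrix(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, sample_a = "sample_b",
                                            sample_b = "sample_a"))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                    fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$d)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "divergence (%)",
                  title = sprintf("Region: %s", attr(object, "region"))) +
    ggplot2::theme_minimal()
}
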