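#' Boxplots of orbital dimensions by morphotype
#'
#' @param cohort Cohort tibble with a type column.
#' @param type_col Grouping column, default `"true_type"`.
#' @return A ggplot object: one panel per dimension.
#' @examples
#' plot_cohort(simulate_cohort(n = 300, seed = 1))
#' @export
plot_cohort <- function(cohort, type_col = "true_type") {
  check_dimension_cols(cohort)
  long <- cohort |>
    dplyr::rename(type = dplyr::all_of(type_col)) |>
    tidyr::pivot_longer(dplyr::all_of(DIM_COLS),
                        names_to = "dimension", values_to = "mm") |>
    dplyr::mutate(dimension = factor(.data$dimension, levels = DIM_COLS,
                                     labels = c("depth (D)", "height (H)",
                                                "width (W)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$mm,
                                     fill = .data$type)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~dimension, scales = "free_y") +
    ggplot2::labs(x = "morphotype", y = "mm",
                  title = "Orbital dimensions by morphotype") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_classification Confusion-matrix heatmap.
#' @param object An `orbit_metrics` object.
#' @exportS3Method ggplot2::autoplot
autoplot.orbit_metrics <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.1f%%)",
                                  100 * object$accuracy),
                  fill = "count") +
    ggplot2::theme_minimal()
}

#' @describeIn optimize_depth_cutoffs Depth histogram with the optimized
#'   cut points and their bootstrap confidence bands.
#' @param object A `depth_cutoffs` object.
#' @exportS3Method ggplot2::autoplot
autoplot.depth_cutoffs <- function(object, ...) {
  df <- tibble::tibble(depth = object$depth, type = object$labels)
  ci <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, fill = .data$type)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = c(object$d1, object$d2),
                        linetype = "dashed") +
    ggplot2::labs(x = "orbital depth (mm)", y = "count",
                  title = "Depth-only cut points") +
    ggplot2::theme_minimal()
  if (!any(is.na(ci$ci_lower))) {
    p <- p + ggplot2::annotate("rect",
                               xmin = ci$ci_lower, xmax = ci$ci_upper,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

#' @describeIn orbit_kmeans Scatter plot of two dimensions coloured by
#'   cluster, with raw-scale centroids marked.
#' @param object An `orbit_kmeans` fit.
#' @param data The cohort the model was fitted to.
#' @exportS3Method ggplot2::autoplot
autoplot.orbit_kmeans <- function(object, data, ...) {
  check_dimension_cols(data)
  df <- dplyr::mutate(tibble::as_tibble(data),
                      cluster = factor(object$cluster))
  cen <- tibble::as_tibble(object$centers_raw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$height_mm, y = .data$depth_mm,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_point(data = cen, ggplot2::aes(x = .data$height_mm,
                                                 y = .data$depth_mm),
                        inherit.aes = FALSE, shape = 4, size = 4,
                        stroke = 1.5) +
    ggplot2::labs(x = "height (mm)", y = "depth (mm)",
                  title = "K-means clusters in the height-depth plane") +
    ggplot2::theme_minimal()
}
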