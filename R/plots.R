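#' Plot a field map
#'
#' Raster plot of the field layout colored by crop class; background pixels
#' are blank.
#'
#' @param fields A [field_map()].
#' @return A ggplot object.
#' @export
plot_field_map <- function(fields) {
  df <- field_pixels_df(fields)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Crop") +
    ggplot2::theme_minimal()
}

field_pixels_df <- function(fields) {
  ids <- fields$field_ids
  keep <- which(ids > 0L)
  lab <- setNames(fields$labels$class, fields$labels$field_id)
  tibble(
    row = (keep - 1L) %% nrow(ids) + 1L,
    col = (keep - 1L) %/% nrow(ids) + 1L,
    field_id = ids[keep],
    class = unname(lab[as.character(ids[keep])])
  )
}

#' @describeIn plot_field_map Autoplot method for field maps.
#' @param object,... A [field_map()]; further arguments ignored.
#' @export
autoplot.field_map <- function(object, ...) plot_field_map(object)

#' Per-field confidence plot for aggregation results
#'
#' Dot plot of the winning-class confidence per field, colored by predicted
#' class -- a quick read on how decisively each strategy labels fields.
#'
#' @param object A `field_aggregation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.field_aggregation <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$predicted_class))
  ggplot2::ggplot(df, ggplot2::aes(.data$confidence,
                                   stats::reorder(factor(.data$field_id),
                                                  .data$confidence),
                                   color = .data$predicted_class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Aggregated confidence", y = "Field",
                  color = "Predicted class",
                  title = paste("Aggregation:",
                                df$method[1] %||% "unknown")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Confusion-matrix heatmap for a metric report
#'
#' @param object A [metric_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "Predicted", y = "True", fill = "Count",
      title = sprintf("%s-level: OA %.1f%%, macro F1 %.3f",
                      object$level, object$overall_accuracy, object$macro_f1)
    ) +
    ggplot2::theme_minimal()
}

#' Benchmark grid summary plot
#'
#' Field-level overall accuracy by aggregation strategy, faceted by
#' classifier, colored by balancing strategy.
#'
#' @param object A `benchmark_grid` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_grid <- function(object, ...) {
  df <- dplyr::filter(object, .data$level == "field")
  df$aggregation <- ifelse(df$aggregation == "bayesian" & !is.na(df$alpha) &
                             df$alpha < 1,
                           sprintf("bayesian (a=%.2f)", df$alpha),
                           df$aggregation)
  ggplot2::ggplot(df, ggplot2::aes(.data$aggregation,
                                   .data$overall_accuracy,
                                   fill = .data$resampling)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$classifier)) +
    ggplot2::labs(x = "Aggregation", y = "Field-level OA (%)",
                  fill = "Balancing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
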