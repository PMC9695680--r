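#' Tidy field-level aggregation results
#'
#' Expands the per-class confidence list column into long form: one row per
#' field and class.
#'
#' @param x A `field_aggregation` tibble from [aggregate_field_map()] or
#'   [aggregate_pixels()].
#' @param ... Unused.
#' @return Tibble with `field_id`, `method`, `class`, `confidence`,
#'   `predicted` (logical).
#' @export
tidy.field_aggregation <- function(x, ...) {
  x |>
    dplyr::filter(!is.na(.data$predicted_class)) |>
    dplyr::mutate(class_confidence = purrr::map(.data$class_confidence,
                                                tibble::enframe,
                                                name = "class",
                                                value = "confidence")) |>
    dplyr::select("field_id", "method", "predicted_class",
                  "class_confidence") |>
    tidyr::unnest("class_confidence") |>
    dplyr::mutate(predicted = .data$class == .data$predicted_class) |>
    dplyr::select("field_id", "method", "class", "confidence", "predicted")
}

#' Summarize field-level aggregation results
#'
#' @inheritParams tidy.field_aggregation
#' @return One-row tibble: `method`, `n_fields`, `n_flagged` (fields with no
#'   usable pixels), `n_ties`, `mean_confidence`.
#' @export
glance.field_aggregation <- function(x, ...) {
  tibble(
    method = x$method[!is.na(x$method)][1],
    n_fields = nrow(x),
    n_flagged = sum(is.na(x$predicted_class)),
    n_ties = sum(x$tie, na.rm = TRUE),
    mean_confidence = mean(x$confidence, na.rm = TRUE)
  )
}
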