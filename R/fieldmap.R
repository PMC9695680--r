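#' Field map: field-ID raster plus field labels
#'
#' A `field_map` pairs an integer raster of field identifiers (0 = background,
#' no field) with a label table assigning each field one crop class. Field
#' pixel sets are disjoint by construction: a pixel carries at most one ID.
#'
#' @param field_ids Integer matrix of field IDs on the pixel grid; 0 marks
#'   background pixels.
#' @param labels Data frame with columns `field_id` and `class`, one row per
#'   field present in the raster.
#'
#' @return An object of class `field_map` with elements `field_ids`, `labels`
#'   (a tibble) and `n_fields`.
#' @export
#' @examples
#' ids <- matrix(c(0, 1, 1, 2), 2, 2)
#' field_map(ids, data.frame(field_id = 1:2, class = c("Maize", "Grass")))
field_map <- function(field_ids, labels) {
  if (!is.matrix(field_ids)) abort("`field_ids` must be a matrix.")
  storage.mode(field_ids) <- "integer"
  if (any(field_ids < 0L, na.rm = TRUE)) {
    abort("Field IDs must be non-negative (0 = background).")
  }
  labels <- as_tibble(labels)
  if (!all(c("field_id", "class") %in% names(labels))) {
    abort("`labels` must have columns `field_id` and `class`.")
  }
  labels$field_id <- as.integer(labels$field_id)
  labels$class <- as.character(labels$class)
  if (any(labels$field_id == 0L)) {
    abort("Background ID 0 must not appear in the label table.")
  }
  dup <- labels$field_id[duplicated(labels$field_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate label rows for field ID(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  present <- setdiff(unique(as.vector(field_ids)), 0L)
  missing <- setdiff(present, labels$field_id)
  if (length(missing)) {
    abort(sprintf("Raster field ID(s) without a label: %s.",
                  paste(sort(missing), collapse = ", ")))
  }
  labels <- labels[labels$field_id %in% present, , drop = FALSE]
  structure(
    list(field_ids = field_ids, labels = labels,
         n_fields = length(present)),
    class = "field_map"
  )
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d x %d pixels, %d fields, %d classes\n",
              nrow(x$field_ids), ncol(x$field_ids), x$n_fields,
              dplyr::n_distinct(x$labels$class)))
  invisible(x)
}

#' Per-field pixel counts
#'
#' @param fields A [field_map()].
#' @return Tibble with `field_id`, `class`, `n_pixels`, sorted by field ID.
#' @export
field_sizes <- function(fields) {
  ids <- fields$field_ids[fields$field_ids > 0L]
  cnt <- table(ids)
  tibble(field_id = as.integer(names(cnt)),
         n_pixels = as.integer(cnt)) |>
    dplyr::left_join(fields$labels, by = "field_id") |>
    dplyr::select("field_id", "class", "n_pixels")
}

#' Ordered class catalog from counts
#'
#' Builds the catalog used for weighting and for deterministic tie-breaking:
#' classes in a fixed order with their (field or pixel) counts.
#'
#' @param counts Named integer vector of per-class counts, or a `field_map`
#'   (field counts are tallied from the label table).
#' @return Tibble with columns `class` and `count`; class order is the order
#'   of `counts` (alphabetical for a `field_map`).
#' @export
#' @examples
#' class_catalog(c(Maize = 251, Grass = 85))
class_catalog <- function(counts) {
  if (inherits(counts, "field_map")) {
    tab <- table(counts$labels$class)
    return(tibble(class = names(tab), count = as.integer(tab)))
  }
  if (is.null(names(counts))) abort("`counts` must be named by class.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  tibble(class = names(counts), count = as.integer(counts))
}
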