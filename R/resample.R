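#' @name pixel-dataset
#' @title Pixel training sets
#' @description
#' Pixel training data is a plain tibble: one row per pixel sample, a
#' `class` column (character or factor), an optional `field_id` provenance
#' column, and numeric feature columns (typically the 17 normalized
#' band/index values). All resampling verbs take and return such tibbles, so
#' they compose with dplyr pipelines.
NULL

feature_cols <- function(data) {
  setdiff(names(data), c("class", "field_id", "row", "col"))
}

check_pixel_data <- function(data) {
  if (!"class" %in% names(data)) abort("`data` must have a `class` column.")
  invisible(data)
}

#' Drop classes from a pixel dataset
#'
#' Removes every sample of the given classes, mirroring the preprocessing
#' rule that discards classes too rare to train on (e.g. `Dates`) or
#' ill-defined mixtures (e.g. `Intercrop`).
#'
#' @param data Pixel tibble (see [pixel-dataset]).
#' @param drop Character vector of class names to remove; must all be
#'   present in the data's class set (or its factor levels).
#' @return The filtered tibble; factor levels, if any, are dropped too.
#' @export
#' @examples
#' d <- tibble::tibble(class = c("a", "b", "c"), x = 1:3)
#' filter_classes(d, "b")
filter_classes <- function(data, drop) {
  check_pixel_data(data)
  known <- if (is.factor(data$class)) levels(data$class) else unique(data$class)
  unknown <- setdiff(drop, known)
  if (length(unknown)) {
    abort(sprintf("Unknown class name(s): %s.", paste(unknown, collapse = ", ")))
  }
  out <- dplyr::filter(data, !(as.character(.data$class) %in% drop))
  if (is.factor(out$class)) out$class <- droplevels(out$class)
  out
}

class_counts <- function(data) {
  tab <- table(as.character(data$class))
  setNames(as.integer(tab), names(tab))
}

#' Random over-sampling to the majority-class count
#'
#' Duplicates samples of each minority class by drawing with replacement
#' until every class matches the pre-resampling maximum count. No new
#' feature values are invented.
#'
#' @param data Pixel tibble (see [pixel-dataset]); every class needs at
#'   least one sample.
#' @param seed Integer seed for reproducibility (optional).
#' @return Balanced tibble; originals first, duplicates appended.
#' @export
random_oversample <- function(data, seed = NULL) {
  check_pixel_data(data)
  cnt <- class_counts(data)
  if (nrow(data) == 0L) return(data)
  target <- max(cnt)
  draw <- function() {
    extra <- purrr::map(names(cnt), function(cl) {
      need <- target - cnt[[cl]]
      if (need == 0L) return(NULL)
      rows <- which(as.character(data$class) == cl)
      data[sample(rows, need, replace = TRUE), , drop = FALSE]
    })
    dplyr::bind_rows(c(list(data), extra))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Random under-sampling to the minority-class count
#'
#' Keeps a without-replacement subset of each class so that all classes
#' match the pre-resampling minimum count.
#'
#' @inheritParams random_oversample
#' @return Balanced tibble, a subset of the input rows.
#' @export
random_undersample <- function(data, seed = NULL) {
  check_pixel_data(data)
  cnt <- class_counts(data)
  if (nrow(data) == 0L) return(data)
  target <- min(cnt)
  draw <- function() {
    keep <- purrr::map(names(cnt), function(cl) {
      rows <- which(as.character(data$class) == cl)
      sort(sample(rows, target, replace = FALSE))
    })
    data[sort(unlist(keep)), , drop = FALSE]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' SMOTE: synthetic minority over-sampling
#'
#' For each minority class, synthetic samples are generated by linear
#' interpolation between a randomly chosen base sample and one of its `k`
#' nearest same-class neighbors (Euclidean distance in feature space):
#' `x_new = x_base + lambda * (x_corr - x_base)` with `lambda ~ U(0, 1)`.
#' Class counts are raised to the pre-resampling maximum.
#'
#' @inheritParams random_oversample
#' @param k_neighbors Neighborhood size (default 5, the original SMOTE
#'   convention). Classes with fewer than `k_neighbors + 1` samples use all
#'   available neighbors, with a warning.
#' @return Balanced tibble. Synthetic rows inherit the base sample's
#'   `field_id` (if present); the attribute `"smote_provenance"` records,
#'   per synthetic row, the base row, neighbor row and `lambda` used, so
#'   segment membership can be audited.
#' @export
smote_oversample <- function(data, k_neighbors = 5, seed = NULL) {
  check_pixel_data(data)
  cnt <- class_counts(data)
  if (nrow(data) == 0L) return(data)
  target <- max(cnt)
  feats <- feature_cols(data)
  if (!length(feats)) abort("No feature columns to interpolate.")

  draw <- function() {
    prov <- list(); synth <- list()
    for (cl in names(cnt)) {
      need <- target - cnt[[cl]]
      if (need == 0L) next
      rows <- which(as.character(data$class) == cl)
      if (length(rows) < 2L) {
        abort(sprintf("Class '%s' has a single sample; SMOTE needs neighbors.", cl))
      }
      k <- min(k_neighbors, length(rows) - 1L)
      if (k < k_neighbors) {
        warn(sprintf("Class '%s': only %d neighbors available (k = %d requested).",
                     cl, k, k_neighbors))
      }
      x <- as.matrix(data[rows, feats])
      dmat <- as.matrix(stats::dist(x))
      diag(dmat) <- Inf
      nn <- apply(dmat, 1L, function(dr) order(dr)[seq_len(k)], simplify = FALSE)
      base_i <- sample.int(length(rows), need, replace = TRUE)
      corr_i <- vapply(base_i, function(b) nn[[b]][sample.int(k, 1L)], integer(1))
      lambda <- runif(need)
      newx <- x[base_i, , drop = FALSE] +
        lambda * (x[corr_i, , drop = FALSE] - x[base_i, , drop = FALSE])
      rowsyn <- data[rows[base_i], , drop = FALSE]
      rowsyn[, feats] <- as.data.frame(newx)
      synth[[cl]] <- rowsyn
      prov[[cl]] <- tibble(class = cl, base_row = rows[base_i],
                           corr_row = rows[corr_i], lambda = lambda)
    }
    out <- dplyr::bind_rows(c(list(data), unname(synth)))
    attr(out, "smote_provenance") <- dplyr::bind_rows(unname(prov))
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Inverse-frequency class weights
#'
#' Adds a `weight` column to a class catalog:
#' `w_y = total / (n_classes * count_y)`, inverse frequency normalized so
#' the count-weighted mean weight is 1 (`sum(count_y * w_y) = total`). These
#' weights feed the weighted loss and the classifiers' native sample
#' weighting.
#'
#' @param catalog Tibble with `class` and `count` columns
#'   (see [class_catalog()]); all counts must be positive.
#' @return The catalog with a `weight` column appended.
#' @export
#' @examples
#' class_weights(class_catalog(c(A = 3, B = 1)))  # weights 2/3 and 2
class_weights <- function(catalog) {
  if (any(catalog$count <= 0)) {
    abort("Every class needs a positive count to receive a weight.")
  }
  dplyr::mutate(catalog,
                weight = sum(.data$count) / (dplyr::n() * .data$count))
}

#' Class-weighted mean loss
#'
#' `L_w = (1 / |D|) * sum_i w_{y_i} * L_i`: the arithmetic mean of
#' per-sample losses, each scaled by its class weight.
#'
#' @param losses Numeric vector of per-sample losses.
#' @param labels Class label per sample.
#' @param catalog Catalog with `class` and `weight` columns
#'   (see [class_weights()]).
#' @return Scalar weighted loss.
#' @export
weighted_loss <- function(losses, labels, catalog) {
  if (length(losses) != length(labels)) {
    abort("`losses` and `labels` must have equal length.")
  }
  if (length(losses) == 0L) abort("Empty loss vector.")
  w <- setNames(catalog$weight, catalog$class)[as.character(labels)]
  if (anyNA(w)) abort("Some labels are missing from the catalog.")
  mean(w * losses)
}
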