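#' Extract a pixel training table from a feature stack and field map
#'
#' One row per valid field pixel: the field's class label, the field ID
#' (provenance for leakage-free splits), pixel coordinates and one column
#' per channel.
#'
#' @param stack A [band_stack()] (typically the 17-channel feature stack).
#' @param fields A [field_map()] on the same grid.
#' @return A pixel tibble (see [pixel-dataset]).
#' @export
extract_pixels <- function(stack, fields) {
  if (!identical(dim(stack$values)[1:2], dim(fields$field_ids))) {
    abort("Feature stack and field map are not aligned.")
  }
  px <- as_tibble(stack)
  idx <- (px$col - 1L) * nrow(fields$field_ids) + px$row
  px$field_id <- as.vector(fields$field_ids)[idx]
  px <- px[px$field_id > 0L, , drop = FALSE]
  lab <- setNames(fields$labels$class, fields$labels$field_id)
  px$class <- unname(lab[as.character(px$field_id)])
  dplyr::relocate(px, "class", "field_id")
}

#' Split fields into training and validation sets
#'
#' The split is by field, stratified by class, so no field ever contributes
#' pixels to both sides -- pixel-level splits would leak near-duplicate
#' neighboring pixels across the boundary. A class with a single field goes
#' to the training side.
#'
#' @param fields A [field_map()], or its label tibble (`field_id`, `class`).
#' @param prop Fraction of fields per class assigned to training
#'   (default 0.7).
#' @param seed Integer seed (optional).
#' @return List with integer vectors `train` and `validation` of field IDs.
#' @export
split_fields <- function(fields, prop = 0.7, seed = NULL) {
  labels <- if (inherits(fields, "field_map")) fields$labels else as_tibble(fields)
  if (prop <= 0 || prop >= 1) abort("`prop` must lie in (0, 1).")
  run <- function() {
    picks <- labels |>
      dplyr::group_by(.data$class) |>
      dplyr::group_map(function(g, key) {
        n_train <- max(1L, round(prop * nrow(g)))
        tr <- g$field_id[sample.int(nrow(g), n_train)]
        list(train = tr, validation = setdiff(g$field_id, tr))
      })
    list(train = sort(unlist(lapply(picks, `[[`, "train"))),
         validation = sort(unlist(lapply(picks, `[[`, "validation"))))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Train a pixel-level probabilistic classifier
#'
#' Thin wrapper over three standard backends -- k-nearest neighbors
#' (`caret::knn3`), random forest (`ranger`) and gradient-boosted trees
#' (`xgboost`) -- that returns calibrated-order class probabilities per
#' pixel. Per-class weights (the `weighting` balancing strategy) are passed
#' to the backend's native mechanism: case weights for the forest, instance
#' weights for boosting; kNN has no weighting mechanism and rejects weights.
#'
#' @param data Pixel tibble (see [pixel-dataset]).
#' @param classifier `"knn"`, `"rf"` or `"gb"`.
#' @param class_weights Optional named per-class weight vector (see
#'   [class_weights()]).
#' @param seed Integer seed for the stochastic backends.
#' @param params Named list of backend hyperparameters. Defaults:
#'   kNN `k = 10`; random forest `num.trees = 100`; boosting
#'   `nrounds = 30`, `max_depth = 4`, `eta = 0.3`.
#' @return Object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(data, classifier = c("knn", "rf", "gb"),
                                   class_weights = NULL, seed = NULL,
                                   params = list()) {
  classifier <- match.arg(classifier)
  check_pixel_data(data)
  feats <- feature_cols(data)
  classes <- sort(unique(as.character(data$class)))
  x <- as.matrix(data[, feats])
  y <- factor(as.character(data$class), classes)
  w <- NULL
  if (!is.null(class_weights)) {
    if (classifier == "knn") {
      abort("kNN has no class-weighting mechanism; use resampling instead.")
    }
    w <- unname(class_weights[as.character(y)])
    if (anyNA(w)) abort("`class_weights` must cover every class present.")
  }
  model <- switch(classifier,
    knn = {
      if (!requireNamespace("caret", quietly = TRUE)) {
        abort("Package 'caret' is required for the kNN backend.")
      }
      caret::knn3(x, y, k = params$k %||% 10L)
    },
    rf = {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        abort("Package 'ranger' is required for the random-forest backend.")
      }
      ranger::ranger(
        x = x, y = y, probability = TRUE,
        num.trees = params$num.trees %||% 100L,
        case.weights = w,
        seed = seed %||% 1L,
        num.threads = 1L
      )
    },
    gb = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        abort("Package 'xgboost' is required for the boosting backend.")
      }
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                     weight = w)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      max_depth = params$max_depth %||% 4L,
                      eta = params$eta %||% 0.3,
                      nthread = 1L,
                      seed = seed %||% 1L),
        data = dtrain,
        nrounds = params$nrounds %||% 30L,
        verbose = 0
      )
    })
  structure(list(backend = classifier, model = model, classes = classes,
                 features = feats),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> backend = %s, %d classes, %d features\n",
              x$backend, length(x$classes), length(x$features)))
  invisible(x)
}

#' Predict per-pixel class probabilities
#'
#' @param object A [train_pixel_classifier()] fit.
#' @param new_data Pixel tibble with the model's feature columns.
#' @param ... Unused.
#' @return Numeric matrix, one row per pixel, one column per class in the
#'   model's catalog order; rows sum to 1.
#' @export
predict.pixel_classifier <- function(object, new_data, ...) {
  x <- as.matrix(new_data[, object$features])
  p <- switch(object$backend,
    knn = stats::predict(object$model, x, type = "prob"),
    rf = stats::predict(object$model, data = x,
                        num.threads = 1L)$predictions,
    gb = {
      raw <- stats::predict(object$model, xgboost::xgb.DMatrix(x))
      if (is.matrix(raw)) raw else {
        matrix(raw, nrow(x), length(object$classes), byrow = TRUE)
      }
    }
  )
  colnames(p) <- object$classes
  # guard against numerical drift off the simplex
  p / rowSums(p)
}
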