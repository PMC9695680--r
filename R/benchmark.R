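#' Configuration for the resampling x classifier x aggregation benchmark
#'
#' @param synthetic A [synthetic_config()] describing the landscape; kept
#'   deliberately small by default so the full grid runs on one CPU in
#'   minutes.
#' @param resamplers Subset of `c("ros", "rus", "smote", "weighting")`.
#' @param classifiers Subset of `c("knn", "rf", "gb")`.
#' @param aggregations Subset of `c("majority", "average", "bayesian")`;
#'   pixel-level (`"none"`) rows are always reported.
#' @param alpha Smoothing factors evaluated for the Bayesian rows
#'   (default `c(1, 0.35)`: unsmoothed and the mid-range recommendation for
#'   7-class problems).
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param split_prop Training fraction of fields (default 0.7).
#' @param max_pixels_per_field Optional cap on pixels sampled per field for
#'   training speed (default 25; `Inf` keeps all).
#' @param classifier_params Named list of per-backend parameter lists.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(synthetic = synthetic_config(n_fields = 120),
                             resamplers = c("ros", "rus", "smote", "weighting"),
                             classifiers = c("knn", "rf", "gb"),
                             aggregations = c("majority", "average", "bayesian"),
                             alpha = c(1, 0.35),
                             k_neighbors = 5,
                             split_prop = 0.7,
                             max_pixels_per_field = 25,
                             classifier_params = list(),
                             seed = 1L) {
  structure(list(synthetic = synthetic, resamplers = resamplers,
                 classifiers = classifiers, aggregations = aggregations,
                 alpha = alpha, k_neighbors = k_neighbors,
                 split_prop = split_prop,
                 max_pixels_per_field = max_pixels_per_field,
                 classifier_params = classifier_params, seed = seed),
            class = "benchmark_config")
}

cap_pixels <- function(data, cap, seed) {
  if (!is.finite(cap)) return(data)
  withr::with_seed(seed, {
    data |>
      dplyr::group_by(.data$field_id) |>
      dplyr::slice_sample(n = cap) |>
      dplyr::ungroup()
  })
}

#' Run the resampling x classifier x aggregation benchmark grid
#'
#' Generates a synthetic landscape, builds the 17-channel feature stack,
#' splits fields 70/30 stratified by class, then for every combination of
#' balancing strategy (ROS, RUS, SMOTE, class weighting) and classifier
#' (kNN, random forest, gradient boosting) trains on the training-field
#' pixels, predicts class probabilities on held-out-field pixels, and
#' reports pixel-level metrics plus field-level metrics for each
#' aggregation strategy. The incompatible kNN x weighting cell is skipped.
#'
#' @param config A [benchmark_config()].
#' @return Tibble of class `benchmark_grid` with columns `resampling`,
#'   `classifier`, `aggregation`, `alpha`, `level`, `overall_accuracy`,
#'   `macro_f1`, `n` and `seed`.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  seed <- as.integer(config$seed)
  syn <- config$synthetic
  syn$seed <- syn$seed %||% seed
  land <- generate_landscape(syn)
  feats <- build_feature_stack(land$bands)
  px <- extract_pixels(feats$stack, land$fields)
  split <- split_fields(land$fields, prop = config$split_prop,
                        seed = seed + 1L)
  if (dplyr::n_distinct(px$class[px$field_id %in% split$train]) <
      dplyr::n_distinct(px$class)) {
    abort("Degenerate split: a class is absent from the training fields.")
  }
  train_px <- cap_pixels(px[px$field_id %in% split$train, , drop = FALSE],
                         config$max_pixels_per_field, seed + 2L)
  val_px <- px[px$field_id %in% split$validation, , drop = FALSE]
  truth_field <- setNames(land$fields$labels$class,
                          land$fields$labels$field_id)

  grid <- tidyr::expand_grid(resampling = config$resamplers,
                             classifier = config$classifiers) |>
    dplyr::filter(!(.data$classifier == "knn" & .data$resampling == "weighting"))

  rows <- purrr::pmap(grid, function(resampling, classifier) {
    cell_seed <- seed + 100L * match(resampling,
                                     c("ros", "rus", "smote", "weighting")) +
      10L * match(classifier, c("knn", "rf", "gb"))
    weights <- NULL
    tr <- switch(resampling,
      ros = random_oversample(train_px, seed = cell_seed),
      rus = random_undersample(train_px, seed = cell_seed),
      smote = smote_oversample(train_px, k_neighbors = config$k_neighbors,
                               seed = cell_seed),
      weighting = {
        cat_ <- class_weights(class_catalog(class_counts(train_px)))
        weights <- setNames(cat_$weight, cat_$class)
        train_px
      })
    fit <- train_pixel_classifier(
      tr, classifier, class_weights = weights, seed = cell_seed,
      params = config$classifier_params[[classifier]] %||% list())
    probs <- predict(fit, val_px)

    pixel_pred <- fit$classes[max.col(probs, ties.method = "first")]
    pix <- glance(metric_report(val_px$class, pixel_pred, level = "pixel"))
    base <- tibble(resampling = resampling, classifier = classifier)
    out <- dplyr::bind_cols(
      base, tibble(aggregation = "none", alpha = NA_real_), pix)

    for (agg in config$aggregations) {
      alphas <- if (agg == "bayesian") config$alpha else NA_real_
      for (a in alphas) {
        res <- aggregate_pixels(probs, val_px$field_id, method = agg,
                                alpha = if (is.na(a)) 1 else a)
        fld <- glance(metric_report(truth_field[as.character(res$field_id)],
                                    res$predicted_class, level = "field"))
        out <- dplyr::bind_rows(out, dplyr::bind_cols(
          base, tibble(aggregation = agg, alpha = a), fld))
      }
    }
    out
  })
  out <- purrr::list_rbind(rows) |>
    dplyr::mutate(seed = seed) |>
    dplyr::relocate("resampling", "classifier", "aggregation", "alpha",
                    "level", "overall_accuracy", "macro_f1", "n", "seed")
  class(out) <- c("benchmark_grid", class(out))
  out
}
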