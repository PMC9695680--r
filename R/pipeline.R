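#' Assemble a full-run configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. Every
#' stochastic stage derives its seed from the global `seed`, so a rerun
#' with the same configuration reproduces all deterministic artifacts
#' bit-identically.
#'
#' @param seed Global integer seed.
#' @param synthetic A [synthetic_config()] (its `seed` is filled from the
#'   global seed when unset).
#' @param probability_source `"classifier"` (train a pixel classifier on a
#'   field split and predict) or `"dirichlet"` (draw probabilities from the
#'   confusion model directly -- isolates the aggregation stage).
#' @param tau Confusion temperature for the Dirichlet source.
#' @param classifier,resampling Backend and balancing strategy for the
#'   classifier source (see [train_pixel_classifier()]).
#' @param aggregation Aggregation method; `alpha` is the smoothing factor
#'   used when the method is `"bayesian"`.
#' @param alpha Smoothing factor in `(0, 1]`.
#' @param split_prop Training fraction of fields.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       synthetic = synthetic_config(n_fields = 60),
                       probability_source = c("dirichlet", "classifier"),
                       tau = 10,
                       classifier = "rf",
                       resampling = "ros",
                       aggregation = "bayesian",
                       alpha = 0.35,
                       split_prop = 0.7) {
  probability_source <- match.arg(probability_source)
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 probability_source = probability_source, tau = tau,
                 classifier = classifier, resampling = resampling,
                 aggregation = aggregation, alpha = alpha,
                 split_prop = split_prop),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `synthetic`
#' key holds [synthetic_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn_args <- raw$synthetic %||% list()
  raw$synthetic <- do.call(synthetic_config, syn_args)
  do.call(run_config, raw)
}

#' Run the full simulate-classify-aggregate-evaluate pipeline
#'
#' Executes, in order: landscape simulation, 17-channel feature generation,
#' per-pixel probability generation (classifier or Dirichlet source),
#' field-level aggregation, and evaluation. All artifacts are written under
#' `out_dir`: `bands.tif`, `fields.tif`, `labels.csv`, `features.tif`,
#' `probs.tif`, `results.csv` (+ JSON sidecars) and `metrics.csv`.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress the resolved-config echo (default `FALSE`).
#' @return Invisibly, a list with `results` (field aggregation tibble),
#'   `metrics` (pixel- and field-level glance rows) and `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!quiet) {
    message("Resolved configuration:")
    message(yaml::as.yaml(unclass_deep(config)))
  }
  seed <- config$seed
  syn <- config$synthetic
  syn$seed <- syn$seed %||% seed

  land <- generate_landscape(syn)
  p_bands <- file.path(out_dir, "bands.tif")
  p_fields <- file.path(out_dir, "fields.tif")
  p_labels <- file.path(out_dir, "labels.csv")
  write_bandstack(land$bands, p_bands)
  write_fieldmap(land$fields, p_fields, p_labels)

  feats <- build_feature_stack(land$bands)
  p_feat <- file.path(out_dir, "features.tif")
  write_bandstack(feats$stack, p_feat)

  classes <- sort(unique(land$fields$labels$class))
  d <- dim(land$fields$field_ids)

  if (config$probability_source == "dirichlet") {
    probs <- generate_pixel_probabilities(land$fields, tau = config$tau,
                                          seed = seed + 1L, classes = classes)
    val_fields <- land$fields$labels$field_id
    pixel_metrics <- NULL
  } else {
    px <- extract_pixels(feats$stack, land$fields)
    split <- split_fields(land$fields, prop = config$split_prop,
                          seed = seed + 1L)
    train_px <- px[px$field_id %in% split$train, , drop = FALSE]
    weights <- NULL
    train_px <- switch(config$resampling,
      ros = random_oversample(train_px, seed = seed + 2L),
      rus = random_undersample(train_px, seed = seed + 2L),
      smote = smote_oversample(train_px, seed = seed + 2L),
      weighting = {
        cat_ <- class_weights(class_catalog(class_counts(train_px)))
        weights <- setNames(cat_$weight, cat_$class)
        train_px
      },
      none = train_px)
    fit <- train_pixel_classifier(train_px, config$classifier,
                                  class_weights = weights, seed = seed + 3L)
    val_px <- px[px$field_id %in% split$validation, , drop = FALSE]
    pmat <- predict(fit, val_px)
    pixel_pred <- fit$classes[max.col(pmat, ties.method = "first")]
    pixel_metrics <- glance(metric_report(val_px$class, pixel_pred,
                                          level = "pixel"))
    probs <- array(1 / length(classes), c(d, length(classes)),
                   dimnames = list(NULL, NULL, classes))
    flat_idx <- (val_px$col - 1L) * d[1] + val_px$row
    for (k in seq_along(classes)) {
      slice <- probs[, , k]
      slice[flat_idx] <- pmat[, k]
      probs[, , k] <- slice
    }
    val_fields <- split$validation
  }
  p_probs <- file.path(out_dir, "probs.tif")
  write_bandstack(band_stack(probs, classes, syn$resolution_m), p_probs)

  results <- aggregate_field_map(probs, land$fields,
                                 method = config$aggregation,
                                 alpha = config$alpha)
  results <- results[results$field_id %in% val_fields, , drop = FALSE]
  p_results <- file.path(out_dir, "results.csv")
  write_results(results, p_results,
                config = list(seed = seed, method = config$aggregation,
                              alpha = config$alpha,
                              source = config$probability_source))

  truth <- setNames(land$fields$labels$class, land$fields$labels$field_id)
  field_metrics <- glance(metric_report(
    truth[as.character(results$field_id)], results$predicted_class,
    level = "field"))
  metrics <- dplyr::bind_rows(pixel_metrics, field_metrics)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(list(results = results, metrics = metrics,
                 paths = list(bands = p_bands, fields = p_fields,
                              labels = p_labels, features = p_feat,
                              probs = p_probs, results = p_results)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
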