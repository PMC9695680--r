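#' Shrink class probabilities toward the uniform distribution
#'
#' Applies the smoothing map
#' `p_hat(k) = alpha * p(k) + (1 - alpha) / (N - 1) * (1 - p(k))`
#' to each probability vector. The map preserves the probability simplex
#' exactly (`sum p_hat = alpha + (1 - alpha) = 1`), is the identity at
#' `alpha = 1`, and for `alpha > 1/N` strictly shrinks toward uniform while
#' preserving the argmax. Smoothing tempers overconfident per-pixel
#' predictions before log-odds aggregation, which is otherwise dominated by
#' probabilities saturated at 0 or 1.
#'
#' @param p Probability vector on the `N`-simplex, or a matrix with one
#'   vector per row.
#' @param alpha Smoothing factor in `(0, 1]`; 1 means no smoothing. For
#'   7-class problems, grid search on held-out fields typically favors
#'   values around 0.3-0.4 (see [tune_alpha()]); the package default used by
#'   [bayesian_vote()] is `alpha = 1` unless set explicitly.
#' @param n_classes Number of classes `N` (>= 2); inferred from `p` when
#'   omitted.
#' @return Smoothed probabilities with the shape of `p`.
#' @export
#' @examples
#' smooth_probabilities(c(1, 0, 0), alpha = 0.3)  # 0.30 0.35 0.35
smooth_probabilities <- function(p, alpha, n_classes = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].")
  }
  n <- n_classes %||% if (is.matrix(p)) ncol(p) else length(p)
  if (n < 2L) abort("Smoothing needs at least two classes.")
  alpha * p + (1 - alpha) / (n - 1) * (1 - p)
}

check_prob_matrix <- function(probs) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (nrow(probs) == 0L) abort("Empty field: no pixels to aggregate.")
  if (ncol(probs) < 2L) abort("Need probabilities over at least two classes.")
  if (any(!is.finite(probs))) abort("Non-finite probability encountered.")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9)) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("Each pixel's probabilities must sum to 1 (within 1e-6).")
  }
  probs
}

vote_result <- function(conf_vec, n_pixels, method, alpha = NA_real_,
                        tie = FALSE) {
  best <- which.max(conf_vec)  # ties -> lowest catalog index
  tibble(
    predicted_class = names(conf_vec)[best],
    confidence = unname(conf_vec[best]),
    n_pixels = as.integer(n_pixels),
    method = method,
    alpha = alpha,
    tie = tie,
    class_confidence = list(conf_vec)
  )
}

class_names_of <- function(probs) {
  colnames(probs) %||% paste0("class_", seq_len(ncol(probs)))
}

#' Majority voting over a field's pixels
#'
#' Each pixel votes for its most probable class; the field receives the
#' modal class. The per-class confidence is the fraction of pixels voting
#' for that class. Ties (equal vote counts) are resolved toward the lowest
#' catalog index (column order) and flagged in the `tie` column. Majority
#' voting ignores how confident each pixel is -- only the argmax matters.
#'
#' @param probs Numeric matrix, one row per pixel, one column per class
#'   (columns in catalog order, named).
#' @return One-row tibble with `predicted_class`, `confidence`, `n_pixels`,
#'   `method`, `alpha`, `tie` and a `class_confidence` list column holding
#'   the full named confidence vector.
#' @export
#' @examples
#' p <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
#' colnames(p) <- c("Maize", "Grass")
#' majority_vote(p)  # Maize, confidence 2/3
majority_vote <- function(probs) {
  probs <- check_prob_matrix(probs)
  cls <- class_names_of(probs)
  votes <- tabulate(max.col(probs, ties.method = "first"), ncol(probs))
  conf <- setNames(votes / nrow(probs), cls)
  tie <- sum(votes == max(votes)) > 1L
  vote_result(conf, nrow(probs), "majority", tie = tie)
}

#' Average voting over a field's pixels
#'
#' The field's confidence in class `k` is the arithmetic mean of the pixel
#' probabilities `p(k | x_i)`; the field label is the argmax of the mean.
#' Averaging uses the full probability vectors but treats pixels as
#' replicate measurements rather than independent evidence: three pixels at
#' 0.6, 0.7 and 0.8 average to 0.7, even though three independent positives
#' should reinforce each other.
#'
#' @inheritParams majority_vote
#' @return One-row tibble as in [majority_vote()].
#' @export
average_vote <- function(probs) {
  probs <- check_prob_matrix(probs)
  conf <- setNames(colMeans(probs), class_names_of(probs))
  tie <- sum(conf == max(conf)) > 1L
  vote_result(conf, nrow(probs), "average", tie = tie)
}

#' Bayesian log-odds aggregation over a field's pixels
#'
#' Treats each pixel's probability as independent evidence and combines it
#' by summing log-odds, one class at a time (one-vs-rest):
#' `I(k) = sum_i log((1 - p(k | x_i)) / p(k | x_i))`,
#' with field confidence `1 / (1 + exp(I(k)))` and the label taken as the
#' class minimizing `I(k)` (identically, maximizing the confidence -- the
#' argmin form avoids overflow for large `|I|`). For a single pixel and
#' `alpha = 1` this reproduces the pixel's own probabilities. Probabilities
#' are clipped to `[eps, 1 - eps]` before the logs so hard 0/1 predictions
#' stay finite; with `alpha < 1` the smoothing of [smooth_probabilities()]
#' is applied first.
#'
#' Aggregated confidences are one-vs-rest and do not sum to 1 across
#' classes; set `renormalize = TRUE` to rescale them to a distribution.
#'
#' @inheritParams majority_vote
#' @param alpha Smoothing factor in `(0, 1]` passed to
#'   [smooth_probabilities()]; 1 disables smoothing.
#' @param eps Probability clip in `(0, 0.5)` (default `1e-9`).
#' @param renormalize Rescale the per-class confidences to sum to 1
#'   (default `FALSE`; the field label is unaffected).
#' @return One-row tibble as in [majority_vote()].
#' @export
#' @examples
#' p <- rbind(c(0.6, 0.4), c(0.7, 0.3), c(0.8, 0.2))
#' colnames(p) <- c("pos", "neg")
#' bayesian_vote(p)$confidence  # 14/15: three weak positives reinforce
bayesian_vote <- function(probs, alpha = 1, eps = 1e-9, renormalize = FALSE) {
  probs <- check_prob_matrix(probs)
  if (!is.numeric(eps) || eps <= 0 || eps >= 0.5) {
    abort("`eps` must lie in (0, 0.5).")
  }
  cls <- class_names_of(probs)
  if (alpha < 1) probs <- smooth_probabilities(probs, alpha)
  p <- pmin(pmax(probs, eps), 1 - eps)
  log_odds_against <- log1p(-p) - log(p)   # log((1-p)/p), per pixel & class
  i_k <- colSums(log_odds_against)
  conf <- setNames(stats::plogis(-i_k), cls)  # 1 / (1 + exp(I(k)))
  tie <- sum(i_k == min(i_k)) > 1L
  if (renormalize) conf <- conf / sum(conf)
  out <- vote_result(conf, nrow(probs), "bayesian", alpha = alpha, tie = tie)
  # argmax of confidence and argmin of I agree; keep the argmin for safety
  out$predicted_class <- cls[which.min(i_k)]
  out
}

#' Aggregate a per-pixel probability raster over a field map
#'
#' Collapses pixel-level class probabilities to one prediction per labeled
#' field using the requested strategy. Background pixels (field ID 0) and
#' invalid pixels are ignored; a field left with no usable pixels yields a
#' flagged row (`predicted_class = NA`) rather than a forced class.
#'
#' @param probs Numeric array `height x width x n_classes` of per-pixel
#'   probabilities; `dimnames(probs)[[3]]` gives the class order (catalog
#'   order, used for tie-breaking).
#' @param fields A [field_map()] on the same pixel grid.
#' @param method One of `"majority"`, `"average"`, `"bayesian"`.
#' @param alpha,eps,renormalize Passed to [bayesian_vote()] (ignored by the
#'   other methods).
#' @param valid_mask Optional logical matrix; `FALSE` pixels are excluded.
#' @return A tibble of class `field_aggregation`: one row per labeled field
#'   with the columns of [majority_vote()] plus `field_id`.
#' @export
aggregate_field_map <- function(probs, fields,
                                method = c("majority", "average", "bayesian"),
                                alpha = 1, eps = 1e-9, renormalize = FALSE,
                                valid_mask = NULL) {
  method <- match.arg(method)
  if (!inherits(fields, "field_map")) abort("`fields` must be a field_map.")
  d <- dim(probs)
  if (length(d) != 3L || !identical(d[1:2], dim(fields$field_ids))) {
    abort("Probability grid and field map are not aligned.")
  }
  cls <- dimnames(probs)[[3]] %||% paste0("class_", seq_len(d[3]))
  flat <- matrix(probs, d[1] * d[2], d[3], dimnames = list(NULL, cls))
  ids <- as.vector(fields$field_ids)
  usable <- ids > 0L
  if (!is.null(valid_mask)) usable <- usable & as.vector(valid_mask)

  one_field <- function(fid) {
    rows <- which(usable & ids == fid)
    p <- flat[rows, , drop = FALSE]
    p <- p[stats::complete.cases(p), , drop = FALSE]
    if (nrow(p) == 0L) {
      return(tibble(predicted_class = NA_character_, confidence = NA_real_,
                    n_pixels = 0L, method = method, alpha = alpha,
                    tie = NA, class_confidence = list(NULL)))
    }
    switch(method,
           majority = majority_vote(p),
           average = average_vote(p),
           bayesian = bayesian_vote(p, alpha = alpha, eps = eps,
                                    renormalize = renormalize))
  }
  fids <- sort(fields$labels$field_id)
  out <- dplyr::bind_cols(tibble(field_id = fids),
                          purrr::list_rbind(purrr::map(fids, one_field)))
  class(out) <- c("field_aggregation", class(out))
  out
}

#' Aggregate per-pixel probabilities grouped by field ID
#'
#' Data-frame-shaped counterpart of [aggregate_field_map()]: takes pixel
#' probabilities as a matrix plus a parallel vector of field IDs and returns
#' one row per field. Useful when pixels come from a classifier's prediction
#' table rather than a raster.
#'
#' @param probs Numeric matrix, one row per pixel, one named column per
#'   class (catalog order).
#' @param field_id Integer vector, one entry per pixel row; 0 rows are
#'   dropped as background.
#' @inheritParams aggregate_field_map
#' @return A `field_aggregation` tibble, one row per distinct field ID.
#' @export
aggregate_pixels <- function(probs, field_id,
                             method = c("majority", "average", "bayesian"),
                             alpha = 1, eps = 1e-9, renormalize = FALSE) {
  method <- match.arg(method)
  if (nrow(probs) != length(field_id)) {
    abort("`field_id` must have one entry per pixel row.")
  }
  keep <- field_id > 0L
  probs <- probs[keep, , drop = FALSE]
  field_id <- field_id[keep]
  fids <- sort(unique(field_id))
  out <- purrr::map(fids, function(fid) {
    p <- probs[field_id == fid, , drop = FALSE]
    switch(method,
           majority = majority_vote(p),
           average = average_vote(p),
           bayesian = bayesian_vote(p, alpha = alpha, eps = eps,
                                    renormalize = renormalize))
  })
  out <- dplyr::bind_cols(tibble(field_id = fids), purrr::list_rbind(out))
  class(out) <- c("field_aggregation", class(out))
  out
}

#' Grid search for the smoothing factor
#'
#' Evaluates Bayesian aggregation at each candidate `alpha` against the
#' field map's true labels and reports the field-level overall accuracy, so
#' the smoothing factor can be tuned on a validation scene.
#'
#' @inheritParams aggregate_field_map
#' @param alphas Numeric vector of candidate smoothing factors in `(0, 1]`.
#' @return Tibble with columns `alpha` and `overall_accuracy` (percent),
#'   one row per candidate, in the order given.
#' @export
tune_alpha <- function(probs, fields, alphas = seq(0.1, 1, by = 0.1),
                       eps = 1e-9) {
  truth <- setNames(fields$labels$class, fields$labels$field_id)
  purrr::map_dfr(alphas, function(a) {
    res <- aggregate_field_map(probs, fields, method = "bayesian",
                               alpha = a, eps = eps)
    tibble(alpha = a,
           overall_accuracy = overall_accuracy(
             truth[as.character(res$field_id)], res$predicted_class))
  })
}
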