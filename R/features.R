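#' Per-channel standardization of a band stack
#'
#' Standardizes every channel to zero mean and unit standard deviation over
#' the valid pixels: `x_hat = (x - mu_j) / sigma_j` with `mu_j`, `sigma_j`
#' the mean and (sample) standard deviation of channel `j`. The statistics
#' are returned so they can be reused on held-out scenes via
#' [apply_normalization()], avoiding train/inference leakage.
#'
#' @param stack A [band_stack()]; every channel needs at least two valid
#'   pixels and nonzero variance.
#' @return A list with elements `stack` (the normalized [band_stack()]) and
#'   `stats` (tibble with `channel`, `mean`, `sd`).
#' @export
#' @examples
#' s <- band_stack(array(runif(32), c(4, 4, 2)), c("B04", "B08"))
#' norm <- normalize_bands(s)
#' norm$stats
normalize_bands <- function(stack) {
  keep <- stack$valid_mask
  if (sum(keep) < 2L) abort("Need at least two valid pixels.")
  nch <- n_channels(stack)
  mu <- numeric(nch); sg <- numeric(nch)
  out <- stack$values
  for (j in seq_len(nch)) {
    v <- stack$values[, , j][keep]
    mu[j] <- mean(v)
    sg[j] <- sd(v)
    if (!is.finite(sg[j]) || sg[j] == 0) {
      abort(sprintf("Channel '%s' has zero variance; cannot normalize.",
                    stack$channel_names[j]))
    }
    out[, , j] <- (stack$values[, , j] - mu[j]) / sg[j]
  }
  list(
    stack = band_stack(out, stack$channel_names, stack$resolution_m,
                       stack$valid_mask),
    stats = tibble(channel = stack$channel_names, mean = mu, sd = sg)
  )
}

#' Apply previously computed normalization statistics
#'
#' @param stack A [band_stack()] whose channels match `stats$channel`.
#' @param stats Tibble from [normalize_bands()].
#' @return The normalized [band_stack()].
#' @export
apply_normalization <- function(stack, stats) {
  if (!identical(stack$channel_names, stats$channel)) {
    abort("Channel names do not match the normalization statistics.")
  }
  out <- stack$values
  for (j in seq_len(n_channels(stack))) {
    out[, , j] <- (stack$values[, , j] - stats$mean[j]) / stats$sd[j]
  }
  band_stack(out, stack$channel_names, stack$resolution_m, stack$valid_mask)
}

# Shared core for the normalized-difference style indices: num/den with a
# fill value and invalidation where the denominator vanishes.
ratio_index <- function(num, den, fill = 0) {
  bad <- !is.finite(den) | den == 0
  out <- num / den
  out[bad] <- fill
  attr(out, "valid") <- !bad
  out
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Input grids differ in shape.")
}

#' Normalized Difference Vegetation Index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)`, the standard greenness index. Where
#' the denominator is zero the pixel gets the fill value 0 and is flagged
#' invalid in the `"valid"` attribute of the result.
#'
#' @param nir,red Reflectance matrices of equal shape (values in `[0, 1]`).
#' @return Matrix of index values in `[-1, 1]`, with a logical `"valid"`
#'   attribute.
#' @export
#' @examples
#' ndvi(matrix(0.8), matrix(0.2))  # 0.6
ndvi <- function(nir, red) {
  check_same_shape(nir, red)
  ratio_index(nir - red, nir + red)
}

#' Two-band Enhanced Vegetation Index
#'
#' `EVI = 2.5 (NIR - Red) / (NIR + 2.4 Red + 1)`, the two-band EVI variant
#' that avoids the blue band. The `+1` term keeps the denominator positive
#' for physical reflectances, so no degenerate pixels arise there.
#'
#' @inheritParams ndvi
#' @return Matrix of index values with a logical `"valid"` attribute.
#' @export
evi2 <- function(nir, red) {
  check_same_shape(nir, red)
  ratio_index(2.5 * (nir - red), nir + 2.4 * red + 1)
}

#' Normalized Difference Red Edge index
#'
#' `NDRE = (NIR - RE) / (NIR + RE)`: NDVI with the red-edge band (band 6)
#' in place of red, sensitive to canopy chlorophyll.
#'
#' @param nir,red_edge Reflectance matrices of equal shape.
#' @return Matrix of index values in `[-1, 1]` with a `"valid"` attribute.
#' @export
ndre <- function(nir, red_edge) {
  check_same_shape(nir, red_edge)
  ratio_index(nir - red_edge, nir + red_edge)
}

#' Modified Soil-Adjusted Vegetation Index
#'
#' The closed-form MSAVI
#' `(2 NIR + 1 - sqrt((2 NIR + 1)^2 - 8 (NIR - Red))) / 2`,
#' which suppresses bare-soil background effects. Pixels with a negative
#' discriminant (impossible for reflectances in `[0, 1]`) are filled with 0
#' and flagged invalid.
#'
#' @inheritParams ndvi
#' @return Matrix of index values with a logical `"valid"` attribute.
#' @export
msavi <- function(nir, red) {
  check_same_shape(nir, red)
  disc <- (2 * nir + 1)^2 - 8 * (nir - red)
  bad <- disc < 0
  disc[bad] <- 0
  out <- (2 * nir + 1 - sqrt(disc)) / 2
  out[bad] <- 0
  attr(out, "valid") <- !bad
  out
}

#' Assemble the 17-channel feature stack
#'
#' Takes the 13 reflectance bands, computes NDVI, EVI, NDRE and MSAVI from
#' the raw (unnormalized) reflectances, appends them as channels 14-17, and
#' standardizes the full 17-channel stack with [normalize_bands()]. Indices
#' are always computed before normalization: ratio indices are meaningless
#' on standardized values.
#'
#' @param stack A 13-channel [band_stack()] of BOA reflectance.
#' @param band_roles Named character vector mapping the roles `NIR`, `Red`
#'   and `RE` to channel names (default `B08`, `B04`, `B06`).
#' @param normalize Standardize the output stack (default `TRUE`). Set to
#'   `FALSE` to inspect raw index channels.
#' @param stats Optional normalization statistics from a previous (training)
#'   scene, applied instead of scene-local statistics.
#' @return A list with `stack` (17-channel [band_stack()]) and `stats`
#'   (tibble, `NULL` when `normalize = FALSE`).
#' @export
build_feature_stack <- function(stack, band_roles = DEFAULT_BAND_ROLES,
                                normalize = TRUE, stats = NULL) {
  if (n_channels(stack) != 13L) {
    abort(sprintf("Expected a 13-band input stack, got %d channels.",
                  n_channels(stack)))
  }
  for (role in c("NIR", "Red", "RE")) {
    if (!band_roles[[role]] %in% stack$channel_names) {
      abort(sprintf("Role %s resolves to '%s', not a channel of the stack.",
                    role, band_roles[[role]]))
    }
  }
  nir <- get_channel(stack, band_roles[["NIR"]])
  red <- get_channel(stack, band_roles[["Red"]])
  re <- get_channel(stack, band_roles[["RE"]])

  idx <- list(ndvi(nir, red), evi2(nir, red), ndre(nir, re), msavi(nir, red))
  mask <- stack$valid_mask
  for (m in idx) mask <- mask & attr(m, "valid")

  d <- dim(stack$values)
  vals <- array(0, c(d[1], d[2], 17L))
  vals[, , 1:13] <- stack$values
  for (j in 1:4) vals[, , 13L + j] <- idx[[j]]
  full <- band_stack(vals, c(stack$channel_names, INDEX_CHANNELS),
                     stack$resolution_m, mask)
  if (!normalize) return(list(stack = full, stats = NULL))
  if (!is.null(stats)) {
    return(list(stack = apply_normalization(full, stats), stats = stats))
  }
  normalize_bands(full)
}
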