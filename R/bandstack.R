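#' Multi-band reflectance stack
#'
#' A `band_stack` holds a pixel grid of co-registered raster channels: the 13
#' Sentinel-2-style reflectance bands, optionally followed by derived
#' spectral-index channels. All channels share one `height x width` grid and a
#' common ground resolution; a per-pixel validity mask marks nodata pixels,
#' which are excluded from every downstream statistic.
#'
#' @param values Numeric array of dimension `c(height, width, n_channels)`, or
#'   a single `height x width` matrix for a one-channel stack.
#' @param channel_names Character vector of unique channel identifiers, one
#'   per slice of `values`. Index channels (`NDVI`, `EVI`, `NDRE`, `MSAVI`)
#'   may only appear after the base bands.
#' @param resolution_m Ground resolution in meters per pixel side (default 10,
#'   the finest Sentinel-2 resolution).
#' @param valid_mask Logical `height x width` matrix; `FALSE` marks nodata
#'   pixels. Defaults to all pixels valid.
#'
#' @return An object of class `band_stack`.
#' @export
#' @examples
#' arr <- array(runif(4 * 4 * 2), c(4, 4, 2))
#' band_stack(arr, c("B04", "B08"))
band_stack <- function(values, channel_names, resolution_m = 10,
                       valid_mask = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a height x width x channels array.")
  }
  d <- dim(values)
  if (length(channel_names) != d[3]) {
    abort(sprintf("%d channel names supplied for %d channels.",
                  length(channel_names), d[3]))
  }
  if (anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique.")
  }
  idx_pos <- which(channel_names %in% INDEX_CHANNELS)
  if (length(idx_pos) && any(diff(c(idx_pos, d[3] + 1L)) != 1L)) {
    abort("Index channels must form the tail of the stack.")
  }
  if (!is.numeric(resolution_m) || length(resolution_m) != 1L ||
      resolution_m <= 0) {
    abort("`resolution_m` must be a single positive number.")
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, d[1], d[2])
  }
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), d[1:2])) {
    abort("`valid_mask` must be a logical matrix matching the pixel grid.")
  }
  dimnames(values) <- list(NULL, NULL, channel_names)
  structure(
    list(values = values, channel_names = as.character(channel_names),
         resolution_m = resolution_m, valid_mask = valid_mask),
    class = "band_stack"
  )
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_stack> %d x %d pixels, %d channels @ %g m\n",
              d[1], d[2], d[3], x$resolution_m))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  n_bad <- sum(!x$valid_mask)
  if (n_bad > 0) cat(sprintf("  nodata pixels: %d\n", n_bad))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$values)

#' Number of channels in a band stack
#' @param stack A [band_stack()].
#' @return Integer channel count.
#' @export
n_channels <- function(stack) dim(stack$values)[3]

#' Extract one channel of a band stack as a matrix
#'
#' @param stack A [band_stack()].
#' @param channel Channel name or integer position.
#' @return A `height x width` numeric matrix.
#' @export
get_channel <- function(stack, channel) {
  if (is.character(channel)) {
    pos <- match(channel, stack$channel_names)
    if (is.na(pos)) abort(sprintf("Channel '%s' not found.", channel))
    channel <- pos
  }
  stack$values[, , channel, drop = TRUE]
}

#' Convert a band stack to a long tibble of pixel values
#'
#' One row per valid pixel, one column per channel, plus `row` and `col`
#' pixel coordinates (1-based).
#'
#' @param x A [band_stack()].
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.band_stack <- function(x, ...) {
  d <- dim(x$values)
  keep <- which(x$valid_mask)
  vals <- apply(x$values, 3L, function(m) m[keep])
  if (length(keep) == 1L) vals <- matrix(vals, nrow = 1L)
  out <- as_tibble(as.data.frame(vals))
  names(out) <- x$channel_names
  dplyr::bind_cols(
    tibble(row = (keep - 1L) %% d[1] + 1L, col = (keep - 1L) %/% d[1] + 1L),
    out
  )
}
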