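#' Read a multi-band raster into a band stack
#'
#' Rasters are stored as multi-frame 32-bit TIFF files. Because baseline TIFF
#' samples live in `[0, 1]`, [write_bandstack()] rescales each channel and
#' records the per-channel scale/offset, channel names, resolution and
#' validity mask in a JSON sidecar (`<path>.json`); `read_bandstack()` undoes
#' the rescaling. A plain TIFF without a sidecar is accepted with default
#' metadata (channels `band_1..n`, 10 m resolution).
#'
#' @param path Path to a TIFF file with at least one frame.
#' @param nodata Optional nodata value: pixels equal to it in every channel
#'   are marked invalid (only used when no sidecar mask is present).
#' @return A [band_stack()].
#' @export
read_bandstack <- function(path, nodata = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0L) abort("Raster has zero bands.")
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f[, , 1L, drop = TRUE] else f
  })
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) abort("Bands do not share a common grid.")

  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(meta) && isTRUE(meta$mask_frame)) {
    mask <- frames[[length(frames)]] > 0.5
    frames <- frames[-length(frames)]
  }
  nch <- length(frames)
  vals <- array(unlist(frames, use.names = FALSE),
                c(dims[[1]][1], dims[[1]][2], nch))
  if (!is.null(meta)) {
    for (j in seq_len(nch)) {
      vals[, , j] <- vals[, , j] * meta$scale[j] + meta$offset[j]
    }
    ch <- meta$channels
    res <- meta$resolution_m
  } else {
    ch <- paste0("band_", seq_len(nch))
    res <- 10
  }
  if (is.null(mask) && !is.null(nodata)) {
    hit <- apply(vals == nodata, c(1, 2), all)
    mask <- !hit
  }
  band_stack(vals, ch, resolution_m = res, valid_mask = mask)
}

#' Write a band stack to disk
#'
#' @param stack A [band_stack()].
#' @param path Output TIFF path; a JSON metadata sidecar is written next to
#'   it at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_bandstack <- function(stack, path) {
  d <- dim(stack$values)
  scale <- numeric(d[3]); offset <- numeric(d[3])
  frames <- vector("list", d[3])
  for (j in seq_len(d[3])) {
    m <- stack$values[, , j]
    lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
    offset[j] <- lo
    scale[j] <- if (hi > lo) hi - lo else 1
    s <- (m - offset[j]) / scale[j]
    s[is.na(s)] <- 0
    frames[[j]] <- s
  }
  has_mask <- !all(stack$valid_mask)
  if (has_mask) frames <- c(frames, list(stack$valid_mask * 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(type = "band_stack", channels = stack$channel_names,
               resolution_m = stack$resolution_m, scale = scale,
               offset = offset, mask_frame = has_mask)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a field map from an ID raster and a label table
#'
#' @param raster_path TIFF of field IDs written by [write_fieldmap()] (or any
#'   single-frame TIFF holding IDs scaled to `[0, 1]` with a sidecar `scale`).
#' @param labels_path CSV with header columns `field_id,class`.
#' @return A [field_map()]. Raster IDs lacking a label row, or duplicate label
#'   rows, raise an error naming the offending IDs.
#' @export
read_fieldmap <- function(raster_path, labels_path) {
  if (!file.exists(raster_path)) abort(sprintf("File not found: %s", raster_path))
  if (!file.exists(labels_path)) abort(sprintf("File not found: %s", labels_path))
  m <- tiff::readTIFF(raster_path)
  if (length(dim(m)) == 3L) m <- m[, , 1L, drop = TRUE]
  side <- paste0(raster_path, ".json")
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    scale <- meta$scale %||% 1
  }
  ids <- matrix(as.integer(round(m * scale)), nrow(m), ncol(m))
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  field_map(ids, labels)
}

#' Write a field map to an ID raster and a label CSV
#'
#' @param fields A [field_map()].
#' @param raster_path Output TIFF path for the ID raster.
#' @param labels_path Output CSV path for the label table.
#' @return `raster_path`, invisibly.
#' @export
write_fieldmap <- function(fields, raster_path, labels_path) {
  mx <- max(1L, max(fields$field_ids))
  tiff::writeTIFF(fields$field_ids / mx, raster_path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(type = "field_map", scale = mx),
                       paste0(raster_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(fields$labels, labels_path, row.names = FALSE, quote = FALSE)
  invisible(raster_path)
}

#' Write field-level aggregation results
#'
#' Writes a CSV with columns `field_id`, `predicted_class`, `confidence`,
#' `strategy` and a JSON sidecar (`<path>.json`) holding the run
#' configuration. An empty result set yields a header-only CSV.
#'
#' @param results Tibble as returned by [aggregate_field_map()].
#' @param path Output CSV path.
#' @param config Optional named list of run settings for the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = list()) {
  out <- tibble(
    field_id = results$field_id %||% integer(),
    predicted_class = results$predicted_class %||% character(),
    confidence = results$confidence %||% numeric(),
    strategy = results$method %||% character()
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(written = format(Sys.time(), tz = "UTC")), config),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back an aggregation result CSV
#'
#' @param path CSV written by [write_results()].
#' @return Tibble with columns `field_id`, `predicted_class`, `confidence`,
#'   `method`.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(field_id = "integer",
                                       predicted_class = "character",
                                       confidence = "numeric",
                                       strategy = "character"))
  tibble(field_id = df$field_id, predicted_class = df$predicted_class,
         confidence = df$confidence, method = df$strategy)
}
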