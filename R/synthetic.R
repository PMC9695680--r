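#' Reference class frequencies for the synthetic landscape
#'
#' Field counts per crop class in the South African Orange River study
#' region that the generator emulates: nine classes with strong imbalance
#' (the largest class holds ~38% of fields, the smallest 2 fields). The two
#' classes unusable for pixel-wise training -- `Dates` (2 fields) and
#' `Intercrop` (a vineyard/pecan mixture) -- are dropped by default,
#' leaving 7 classes.
#'
#' @param include_rare Keep `Dates` and `Intercrop` (default `FALSE`).
#' @return Named integer vector of field counts.
#' @export
#' @examples
#' reference_class_counts()          # 7 retained classes
#' reference_class_counts(TRUE)      # all 9
reference_class_counts <- function(include_rare = FALSE) {
  counts <- c(Cotton = 113L, Dates = 2L, Grass = 85L, Lucern = 468L,
              Maize = 251L, Pecan = 135L, Vacant = 233L, Vineyard = 789L,
              Intercrop = 71L)
  if (include_rare) counts else counts[!names(counts) %in% c("Dates", "Intercrop")]
}

# Class-dependent 13-band BOA reflectance prototypes, built as mixtures of a
# green-vegetation and a bare-soil endmember with small class-specific NIR
# and SWIR offsets so classes are separable but overlapping.
class_prototypes <- function(classes) {
  veg <- c(0.03, 0.04, 0.07, 0.05, 0.12, 0.28, 0.35, 0.40, 0.42,
           0.15, 0.01, 0.20, 0.10)
  soil <- c(0.06, 0.09, 0.13, 0.18, 0.22, 0.25, 0.27, 0.30, 0.31,
            0.12, 0.01, 0.38, 0.30)
  pars <- list( # veg fraction, NIR offset, SWIR offset
    Cotton    = c(0.60, +0.03, +0.04),
    Dates     = c(0.70, -0.02, +0.02),
    Grass     = c(0.75, -0.04, -0.02),
    Lucern    = c(0.90, +0.05, -0.03),
    Maize     = c(0.85, +0.08, 0.00),
    Pecan     = c(0.70, 0.00, -0.05),
    Vacant    = c(0.05, 0.00, +0.05),
    Vineyard  = c(0.50, -0.03, -0.04),
    Intercrop = c(0.60, +0.02, -0.02)
  )
  proto <- vapply(classes, function(cl) {
    p <- pars[[cl]]
    if (is.null(p)) {
      # unknown class: hash the name into a reproducible veg fraction
      f <- (sum(utf8ToInt(cl)) %% 71) / 100 + 0.15
      p <- c(f, 0, 0)
    }
    s <- p[1] * veg + (1 - p[1]) * soil
    s[7:9] <- s[7:9] + p[2]   # B07, B08, B8A
    s[12:13] <- s[12:13] + p[3] # B11, B12
    pmin(pmax(s, 0), 1)
  }, numeric(13))
  rownames(proto) <- S2_BANDS
  proto
}

#' Configuration for the synthetic landscape generator
#'
#' Defaults mirror the structure of the emulated survey: fields of about 150
#' pixels at 10 m resolution (0.015 km2 each) and the 7-class imbalance of
#' [reference_class_counts()].
#'
#' @param n_fields Number of fields to grow (default 300).
#' @param class_proportions Named numeric vector of class proportions
#'   (normalized internally); defaults to the retained-class field counts.
#' @param mean_field_size Mean field area in pixels (default 150).
#' @param size_dispersion Standard deviation of field sizes in pixels
#'   (default 45, i.e. 30% of the mean).
#' @param noise_sd Within-class per-band Gaussian reflectance noise
#'   (default 0.02).
#' @param fill_fraction Fraction of the grid covered by fields; sets the
#'   grid size (default 0.55).
#' @param resolution_m Meters per pixel side (default 10).
#' @param height,width Optional explicit grid size (pixels); overrides
#'   `fill_fraction`.
#' @param seed Integer seed; the same seed reproduces the landscape
#'   bit-identically.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_fields = 300,
                             class_proportions = NULL,
                             mean_field_size = 150,
                             size_dispersion = 45,
                             noise_sd = 0.02,
                             fill_fraction = 0.55,
                             resolution_m = 10,
                             height = NULL, width = NULL,
                             seed = NULL) {
  if (is.null(class_proportions)) {
    cnt <- reference_class_counts()
    class_proportions <- cnt / sum(cnt)
  }
  if (is.null(names(class_proportions))) {
    abort("`class_proportions` must be named by class.")
  }
  class_proportions <- class_proportions / sum(class_proportions)
  if (mean_field_size < 1) abort("`mean_field_size` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(n_fields = n_fields, class_proportions = class_proportions,
                 mean_field_size = mean_field_size,
                 size_dispersion = size_dispersion, noise_sd = noise_sd,
                 fill_fraction = fill_fraction, resolution_m = resolution_m,
                 height = height, width = width, seed = seed),
            class = "synthetic_config")
}

# Grow disjoint contiguous fields on an h x w grid by seeded random region
# growing (4-connectivity): claim a random frontier pixel until the target
# size is reached or the field is boxed in.
grow_fields <- function(h, w, sizes) {
  grid <- integer(h * w)
  free <- rep(TRUE, h * w)
  neighbors <- function(i) {
    r <- (i - 1L) %% h + 1L
    cc <- (i - 1L) %/% h + 1L
    c(if (r > 1L) i - 1L, if (r < h) i + 1L,
      if (cc > 1L) i - h, if (cc < w) i + h)
  }
  for (f in seq_along(sizes)) {
    cand <- which(free)
    if (!length(cand)) break
    s <- cand[sample.int(length(cand), 1L)]
    grid[s] <- f
    free[s] <- FALSE
    frontier <- neighbors(s)
    frontier <- frontier[free[frontier]]
    sz <- 1L
    while (sz < sizes[f] && length(frontier)) {
      pick <- sample.int(length(frontier), 1L)
      j <- frontier[pick]
      frontier <- frontier[-pick]
      if (!free[j]) next
      grid[j] <- f
      free[j] <- FALSE
      sz <- sz + 1L
      nn <- neighbors(j)
      frontier <- c(frontier, nn[free[nn]])
    }
  }
  matrix(grid, h, w)
}

#' Generate a labeled synthetic multispectral landscape
#'
#' Grows disjoint contiguous fields by seeded region growing on a background
#' of bare soil, assigns each field a crop class by the configured
#' proportions, and fills every pixel with the class's 13-band reflectance
#' prototype plus independent Gaussian noise. The output emulates the
#' structure of a single resampled Sentinel-2 scene over smallholder
#' agriculture; it makes no claim to radiative realism.
#'
#' @param config A [synthetic_config()].
#' @return List with `bands` (a 13-channel [band_stack()]) and `fields`
#'   (a [field_map()]).
#' @export
#' @examples
#' sc <- synthetic_config(n_fields = 20, mean_field_size = 30, seed = 1)
#' land <- generate_landscape(sc)
#' land$fields$n_fields
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run <- function() {
    n <- config$n_fields
    target_px <- n * config$mean_field_size
    h <- config$height %||% ceiling(sqrt(target_px / config$fill_fraction))
    w <- config$width %||% h
    if (h * w < target_px) {
      abort(sprintf("Grid %d x %d too small for %d fields of mean size %g.",
                    h, w, n, config$mean_field_size))
    }
    sizes <- pmax(5L, round(rnorm(n, config$mean_field_size,
                                  config$size_dispersion)))
    ids <- grow_fields(h, w, sizes)
    classes <- names(config$class_proportions)
    labels <- tibble(
      field_id = seq_len(n),
      class = sample(classes, n, replace = TRUE,
                     prob = config$class_proportions)
    )
    labels <- labels[labels$field_id %in% ids, , drop = FALSE]
    fm <- field_map(ids, labels)

    proto <- class_prototypes(classes)
    soil <- class_prototypes("Vacant")[, 1]
    vals <- array(0, c(h, w, 13L))
    flat_ids <- as.vector(ids)
    lab_by_id <- setNames(labels$class, labels$field_id)
    inside <- flat_ids > 0L
    classes_flat <- lab_by_id[as.character(flat_ids[inside])]
    for (j in 1:13) {
      base <- rep(soil[j], length(flat_ids))
      base[inside] <- proto[j, classes_flat]
      noise <- if (config$noise_sd > 0) rnorm(h * w, 0, config$noise_sd) else 0
      vals[, , j] <- matrix(pmin(pmax(base + noise, 0), 1), h, w)
    }
    list(bands = band_stack(vals, S2_BANDS, config$resolution_m),
         fields = fm)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' Generate per-pixel class probabilities with controlled confusion
#'
#' Emulates the output of a pixel classifier under the conditional
#' independence assumption of log-odds aggregation: for every field pixel,
#' a probability vector is drawn from a Dirichlet distribution whose
#' concentration on the true class is `1 + 2 / tau` (all other components
#' 1). `tau = 0` yields exact one-hot truth; as `tau` grows the draws
#' approach a flat Dirichlet and per-pixel argmax accuracy falls toward
#' `1/N`. Pixels are independent given the field class; background pixels
#' get the uniform vector.
#'
#' @param fields A [field_map()].
#' @param tau Confusion temperature `>= 0`.
#' @param seed Integer seed (optional).
#' @param classes Class order for the probability slices; defaults to the
#'   sorted distinct labels (the [class_catalog()] order).
#' @return Array `height x width x n_classes` with class names on the third
#'   dimension.
#' @export
generate_pixel_probabilities <- function(fields, tau = 10, seed = NULL,
                                         classes = NULL) {
  if (tau < 0) abort("`tau` must be >= 0.")
  classes <- classes %||% sort(unique(fields$labels$class))
  n <- length(classes)
  if (n < 2L) abort("Need at least two classes.")
  ids <- as.vector(fields$field_ids)
  lab_by_id <- setNames(match(fields$labels$class, classes),
                        fields$labels$field_id)
  true_k <- ifelse(ids > 0L, lab_by_id[as.character(ids)], NA_integer_)
  npix <- length(ids)
  run <- function() {
    p <- matrix(1 / n, npix, n)
    inside <- which(!is.na(true_k))
    if (length(inside)) {
      if (tau == 0) {
        p[inside, ] <- 0
        p[cbind(inside, true_k[inside])] <- 1
      } else {
        a_true <- 1 + 2 / tau
        g <- matrix(rgamma(length(inside) * n, shape = 1), length(inside), n)
        g[cbind(seq_along(inside), true_k[inside])] <-
          rgamma(length(inside), shape = a_true)
        p[inside, ] <- g / rowSums(g)
      }
    }
    array(p, c(dim(fields$field_ids), n),
          dimnames = list(NULL, NULL, classes))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

reflect_pad_index <- function(n, pad) {
  # reflect-101 (edge pixel not duplicated): ... 3 2 | 1 2 3 ... n | n-1 n-2 ...
  c(seq(pad + 1L, 2L), seq_len(n), seq(n - 1L, n - pad))
}

#' Randomized geometric augmentation of an image tile
#'
#' Applies the training-time augmentation pipeline for 100 x 100 pixel
#' tiles, in order: reflection-pad by 50 pixels per side; rotate by a random
#' angle in (-60, 60) degrees; scale by a random factor in (0.75, 1); shift
#' by random offsets in (-20, 20) pixels along both axes; center-crop back
#' to the tile size. Image channels are interpolated bilinearly; the label
#' raster uses order-0 (nearest-neighbor) interpolation so no new label
#' values can appear.
#'
#' @param image A [band_stack()] tile of size `tile_size x tile_size`.
#' @param labels Integer matrix of the same size (e.g. field IDs or class
#'   codes).
#' @param seed Integer seed (optional).
#' @param tile_size Expected tile side in pixels (default 100).
#' @param params Optional fixed transform parameters overriding the random
#'   draw: a list with `angle_deg`, `scale` and `shift` (length-2). With
#'   `angle_deg = 0`, `scale = 1`, `shift = c(0, 0)` the pipeline is the
#'   identity on labels and reproduces the image up to interpolation.
#' @return List with `image` (augmented [band_stack()]), `labels`
#'   (augmented integer matrix), both at the input size, and `params`
#'   (the drawn transform parameters).
#' @export
augment_tile <- function(image, labels, seed = NULL, tile_size = 100L,
                         params = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("Package 'EBImage' is required for augmentation.")
  }
  d <- dim(image$values)
  if (d[1] != tile_size || d[2] != tile_size) {
    abort(sprintf("Expected a %d x %d tile, got %d x %d.",
                  tile_size, tile_size, d[1], d[2]))
  }
  if (!identical(dim(labels), d[1:2])) {
    abort("`labels` must match the image grid.")
  }
  pad <- min(50L, tile_size - 1L)  # reflect-101 cannot exceed n - 1
  run <- function() {
    if (is.null(params)) {
      angle <- runif(1, -60, 60) * pi / 180
      scale <- runif(1, 0.75, 1)
      shift <- runif(2, -20, 20)
    } else {
      angle <- params$angle_deg * pi / 180
      scale <- params$scale
      shift <- params$shift
    }
    idx <- reflect_pad_index(tile_size, pad)
    np <- tile_size + 2L * pad
    ctr <- (np + 1) / 2
    a_mat <- scale * rbind(c(cos(angle), -sin(angle)),
                           c(sin(angle), cos(angle)))
    offset <- c(ctr, ctr) - a_mat %*% c(ctr, ctr) + shift
    m <- rbind(t(a_mat), as.vector(offset))
    crop <- pad + seq_len(tile_size)

    warp <- function(mat, filter) {
      padded <- mat[idx, idx]
      out <- EBImage::affine(padded, m, filter = filter, bg.col = 0)
      as.matrix(out)[crop, crop]
    }
    vals <- array(0, d)
    for (j in seq_len(d[3])) {
      vals[, , j] <- warp(image$values[, , j], "bilinear")
    }
    new_labels <- matrix(as.integer(round(warp(labels * 1, "none"))),
                         tile_size, tile_size)
    list(image = band_stack(vals, image$channel_names, image$resolution_m),
         labels = new_labels,
         params = c(angle_deg = angle * 180 / pi, scale = scale,
                    shift_row = shift[1], shift_col = shift[2]))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
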