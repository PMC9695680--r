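# Shared fixture builders: everything is generated in code at test time.

# Small reflectance stack with the full 13-band layout.
make_stack13 <- function(h = 8, w = 8, seed = 42) {
  withr::with_seed(seed, {
    vals <- array(runif(h * w * 13, 0.01, 0.6), c(h, w, 13))
    band_stack(vals, fieldagg:::S2_BANDS)
  })
}

# Tiny field map: a left field and a right field on a h x w grid.
make_two_fields <- function(h = 4, w = 6,
                            classes = c("Maize", "Grass")) {
  ids <- matrix(0L, h, w)
  ids[, 1:2] <- 1L
  ids[, (w - 1):w] <- 2L
  field_map(ids, data.frame(field_id = 1:2, class = classes))
}

# Random probability matrix on the simplex: n pixels x k classes.
random_simplex <- function(n, k, seed = NULL, names = LETTERS[seq_len(k)]) {
  draw <- function() {
    g <- matrix(rgamma(n * k, shape = 1), n, k)
    p <- g / rowSums(g)
    colnames(p) <- names
    p
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Pixel tibble with gaussian class clusters, for resampling tests.
make_pixel_data <- function(counts = c(A = 30, B = 12, C = 5),
                            n_features = 3, seed = 7) {
  withr::with_seed(seed, {
    rows <- purrr::imap(counts, function(n, cl) {
      center <- which(names(counts) == cl) * 3
      feats <- matrix(rnorm(n * n_features, center), n, n_features)
      colnames(feats) <- paste0("f", seq_len(n_features))
      dplyr::bind_cols(
        tibble::tibble(class = rep(cl, n),
                       field_id = sample(1:5, n, replace = TRUE)),
        tibble::as_tibble(as.data.frame(feats))
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Independent brute-force posterior for binary odds-product aggregation:
# prod(p) / (prod(p) + prod(1 - p)), the naive-Bayes posterior with a
# uniform prior. Stays separate from the log-odds implementation.
odds_product_posterior <- function(p) {
  prod(p) / (prod(p) + prod(1 - p))
}
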