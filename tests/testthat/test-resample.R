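test_that("class filtering removes exactly the named classes", {
  d <- make_pixel_data(c(A = 10, B = 5, C = 3, D = 2))
  out <- filter_classes(d, c("B", "D"))
  expect_setequal(unique(out$class), c("A", "C"))
  expect_equal(nrow(out), 13)
  expect_identical(filter_classes(d, character()), d)
  expect_equal(nrow(filter_classes(d, c("A", "B", "C", "D"))), 0)
  expect_error(filter_classes(d, "Zebra"), "Zebra")
})

test_that("ROS balances to the majority count using only copies", {
  d <- make_pixel_data(c(A = 30, B = 12, C = 5))
  out <- random_oversample(d, seed = 1)
  cnt <- table(out$class)
  expect_true(all(cnt == 30))
  # every output row is an exact copy of an input row
  key <- function(x) do.call(paste, c(x[setdiff(names(x), "class")], sep = "|"))
  expect_true(all(key(out) %in% key(d)))
  # balanced input passes through unchanged
  bal <- make_pixel_data(c(A = 8, B = 8))
  expect_identical(random_oversample(bal, seed = 3), bal)
})

test_that("RUS balances to the minority count without duplication", {
  d <- make_pixel_data(c(A = 30, B = 12, C = 5))
  out <- random_undersample(d, seed = 1)
  expect_true(all(table(out$class) == 5))
  expect_equal(nrow(dplyr::distinct(out)), nrow(out))
  bal <- make_pixel_data(c(A = 8, B = 8))
  expect_identical(random_undersample(bal, seed = 3), bal)
})

test_that("SMOTE synthetics lie on segments between same-class neighbors", {
  d <- make_pixel_data(c(A = 40, B = 15), n_features = 4)
  out <- smote_oversample(d, k_neighbors = 5, seed = 2)
  expect_true(all(table(out$class) == 40))
  prov <- attr(out, "smote_provenance")
  expect_equal(nrow(prov), 25)
  feats <- paste0("f", 1:4)
  synth <- as.matrix(out[(nrow(d) + 1):nrow(out), feats])
  base <- as.matrix(d[prov$base_row, feats])
  corr <- as.matrix(d[prov$corr_row, feats])
  # exact reconstruction from (base, corr, lambda)
  expect_equal(synth, base + prov$lambda * (corr - base),
               ignore_attr = TRUE, tolerance = 1e-12)
  # coordinate-wise convexity
  expect_true(all(synth >= pmin(base, corr) - 1e-12))
  expect_true(all(synth <= pmax(base, corr) + 1e-12))
  # neighbors share the base sample's class
  expect_identical(as.character(d$class[prov$corr_row]), prov$class)
})

test_that("SMOTE handles tiny classes and rejects singletons", {
  d <- make_pixel_data(c(A = 10, B = 3))
  expect_warning(out <- smote_oversample(d, k_neighbors = 5, seed = 1),
                 "neighbors")
  expect_true(all(table(out$class) == 10))
  d1 <- make_pixel_data(c(A = 5, B = 1))
  expect_error(suppressWarnings(smote_oversample(d1, seed = 1)), "single")
})

test_that("1-D SMOTE endpoints behave as the interpolation formula dictates", {
  d <- tibble::tibble(class = c(rep("A", 5), "B", "B"),
                      f1 = c(1:5, 0, 1))
  out <- smote_oversample(d, k_neighbors = 1, seed = 4)
  synth <- out$f1[(nrow(d) + 1):nrow(out)]
  expect_true(all(synth >= 0 & synth <= 1))  # convexity on {0, 1}
})

test_that("resampling is deterministic under a fixed seed and label-preserving", {
  d <- make_pixel_data(c(A = 25, B = 9, C = 6))
  for (f in list(random_oversample, random_undersample,
                 function(x, seed) smote_oversample(x, seed = seed))) {
    a <- f(d, seed = 123)
    b <- f(d, seed = 123)
    expect_identical(a, b)
    expect_setequal(unique(a$class), c("A", "B", "C"))
  }
})

test_that("class weights are normalized inverse frequencies", {
  cat_ <- class_weights(class_catalog(c(A = 3, B = 1)))
  expect_equal(cat_$weight, c(2 / 3, 2))
  expect_equal(sum(cat_$count * cat_$weight), sum(cat_$count))
  bal <- class_weights(class_catalog(c(A = 5, B = 5, C = 5)))
  expect_true(all(bal$weight == 1))
  expect_error(class_weights(class_catalog(c(A = 1, B = 0))), "positive")
})

test_that("the weighted loss reduces to hand-computed values", {
  cat_ <- class_weights(class_catalog(c(A = 3, B = 1)))
  expect_equal(weighted_loss(c(1, 1), c("A", "B"), cat_), 4 / 3)
  expect_equal(weighted_loss(0.5, "B", cat_), 1.0)
  bal <- class_weights(class_catalog(c(A = 2, B = 2)))
  losses <- c(0.2, 0.4, 0.9, 0.1)
  expect_equal(weighted_loss(losses, c("A", "B", "A", "B"), bal),
               mean(losses))
})
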