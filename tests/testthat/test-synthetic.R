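test_that("landscapes are reproducible and structurally valid", {
  sc <- synthetic_config(n_fields = 40, mean_field_size = 40, seed = 11)
  a <- generate_landscape(sc)
  b <- generate_landscape(sc)
  expect_identical(a$bands$values, b$bands$values)
  expect_identical(a$fields$field_ids, b$fields$field_ids)
  expect_identical(a$fields$labels, b$fields$labels)
  expect_equal(n_channels(a$bands), 13)
  # fields are disjoint by construction and all labeled
  ids <- a$fields$field_ids
  expect_true(all(sort(setdiff(unique(as.vector(ids)), 0L)) %in%
                    a$fields$labels$field_id))
  expect_true(all(a$bands$values >= 0 & a$bands$values <= 1))
})

test_that("fields are contiguous under 4-connectivity", {
  sc <- synthetic_config(n_fields = 15, mean_field_size = 30, seed = 21)
  land <- generate_landscape(sc)
  ids <- land$fields$field_ids
  for (f in head(land$fields$labels$field_id, 5)) {
    px <- which(ids == f, arr.ind = TRUE)
    # flood fill from the first pixel must reach all of them
    seen <- 1L
    frontier <- 1L
    repeat {
      nb <- integer()
      for (i in frontier) {
        d <- abs(px[, 1] - px[i, 1]) + abs(px[, 2] - px[i, 2])
        nb <- union(nb, setdiff(which(d == 1L), seen))
      }
      if (!length(nb)) break
      seen <- c(seen, nb)
      frontier <- nb
    }
    expect_equal(length(seen), nrow(px))
  }
})

test_that("zero noise reproduces class prototypes exactly", {
  sc <- synthetic_config(n_fields = 10, mean_field_size = 20,
                         noise_sd = 0, seed = 3)
  land <- generate_landscape(sc)
  proto <- fieldagg:::class_prototypes(names(sc$class_proportions))
  f1 <- land$fields$labels$field_id[1]
  cls <- land$fields$labels$class[1]
  px <- which(land$fields$field_ids == f1)
  for (j in c(1, 8, 13)) {
    ch <- land$bands$values[, , j]
    expect_true(all(ch[px] == proto[j, cls]))
  }
})

test_that("mean field size tracks the configured 150-pixel average", {
  means <- vapply(1:20, function(s) {
    sc <- synthetic_config(n_fields = 50, mean_field_size = 150, seed = s)
    mean(field_sizes(generate_landscape(sc)$fields)$n_pixels)
  }, numeric(1))
  expect_lt(abs(mean(means) - 150) / 150, 0.10)
})

test_that("generated class frequencies follow the configured imbalance", {
  cnt <- reference_class_counts()
  expect_equal(length(cnt), 7)
  sc <- synthetic_config(n_fields = 2000, mean_field_size = 8,
                         size_dispersion = 2, seed = 31)
  land <- generate_landscape(sc)
  obs <- table(factor(land$fields$labels$class, names(cnt)))
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = cnt / sum(cnt)))
  expect_gt(gof$p.value, 0.01)
})

test_that("tau = 0 probabilities are one-hot truth and all methods recover it", {
  sc <- synthetic_config(n_fields = 25, mean_field_size = 25, seed = 41)
  land <- generate_landscape(sc)
  probs <- generate_pixel_probabilities(land$fields, tau = 0, seed = 41)
  truth <- setNames(land$fields$labels$class, land$fields$labels$field_id)
  for (m in c("majority", "average", "bayesian")) {
    res <- aggregate_field_map(probs, land$fields, method = m)
    expect_equal(overall_accuracy(truth[as.character(res$field_id)],
                                  res$predicted_class), 100)
  }
  flat <- matrix(probs, ncol = dim(probs)[3])
  inside <- as.vector(land$fields$field_ids) > 0
  expect_true(all(flat[inside, ] %in% c(0, 1)))
})

test_that("large tau drives per-pixel accuracy toward chance", {
  sc <- synthetic_config(n_fields = 60, mean_field_size = 60, seed = 51)
  land <- generate_landscape(sc)
  probs <- generate_pixel_probabilities(land$fields, tau = 40, seed = 51)
  classes <- dimnames(probs)[[3]]
  flat <- matrix(probs, ncol = length(classes))
  ids <- as.vector(land$fields$field_ids)
  lab <- setNames(land$fields$labels$class, land$fields$labels$field_id)
  inside <- ids > 0
  pred <- classes[max.col(flat[inside, ], ties.method = "first")]
  acc <- mean(pred == lab[as.character(ids[inside])])
  expect_lt(acc, 0.25)
  expect_gt(acc, 1 / length(classes) - 0.05)
  # reproducibility
  probs2 <- generate_pixel_probabilities(land$fields, tau = 40, seed = 51)
  expect_identical(probs, probs2)
})

test_that("probability draws live on the simplex", {
  fm <- make_two_fields()
  probs <- generate_pixel_probabilities(fm, tau = 5, seed = 6)
  flat <- matrix(probs, ncol = 2)
  expect_equal(rowSums(flat), rep(1, nrow(flat)), tolerance = 1e-12)
  expect_true(all(flat >= 0))
  expect_error(generate_pixel_probabilities(fm, tau = -1), "tau")
})
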