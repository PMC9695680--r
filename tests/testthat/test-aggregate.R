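test_that("smoothing preserves the simplex, identity at alpha = 1", {
  expect_equal(smooth_probabilities(c(1, 0, 0), alpha = 0.3),
               c(0.30, 0.35, 0.35))
  p <- c(0.2, 0.5, 0.3)
  expect_identical(smooth_probabilities(p, alpha = 1), p)
  withr::with_seed(5, {
    for (rep in 1:25) {
      k <- sample(2:9, 1)
      p <- random_simplex(4, k)
      a <- runif(1, 0.05, 1)
      sm <- smooth_probabilities(p, alpha = a)
      expect_equal(rowSums(sm), rep(1, 4), tolerance = 1e-12)
      expect_true(all(sm >= 0 & sm <= 1))
    }
  })
  expect_error(smooth_probabilities(c(0.5, 0.5), alpha = 0), "alpha")
  expect_error(smooth_probabilities(c(0.5, 0.5), alpha = 1.2), "alpha")
  expect_error(smooth_probabilities(1, alpha = 0.5), "two classes")
})

test_that("smoothing with alpha above 1/N preserves each pixel's argmax", {
  withr::with_seed(6, {
    p <- random_simplex(200, 7)
    sm <- smooth_probabilities(p, alpha = 0.35)  # 0.35 > 1/7
    expect_identical(max.col(sm, ties.method = "first"),
                     max.col(p, ties.method = "first"))
    # and strictly shrinks toward uniform
    expect_true(all(abs(sm - 1 / 7) <= abs(p - 1 / 7) + 1e-12))
  })
})

test_that("majority voting counts argmax votes and flags ties", {
  p <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  colnames(p) <- c("A", "B")
  r <- majority_vote(p)
  expect_identical(r$predicted_class, "A")
  expect_equal(r$confidence, 2 / 3)
  expect_false(r$tie)

  single <- majority_vote(p[3, , drop = FALSE])
  expect_identical(single$predicted_class, "B")

  tied <- majority_vote(rbind(c(0.9, 0.1), c(0.3, 0.7)))
  expect_true(tied$tie)
  expect_identical(tied$predicted_class, "class_1")  # lowest catalog index
  expect_equal(unname(tied$class_confidence[[1]]), c(0.5, 0.5))
})

test_that("majority voting depends only on per-pixel argmaxes", {
  withr::with_seed(8, {
    p <- random_simplex(40, 5)
    onehot <- t(apply(p, 1, function(r) {
      z <- numeric(5); z[which.max(r)] <- 1; z
    }))
    colnames(onehot) <- colnames(p)
    expect_identical(majority_vote(p)$predicted_class,
                     majority_vote(onehot)$predicted_class)
    expect_equal(majority_vote(p)$class_confidence[[1]],
                 majority_vote(onehot)$class_confidence[[1]])
  })
})

test_that("average voting is the arithmetic mean of pixel probabilities", {
  p <- rbind(c(0.6, 0.4), c(0.7, 0.3), c(0.8, 0.2))
  colnames(p) <- c("A", "B")
  r <- average_vote(p)
  expect_equal(r$confidence, 0.7)
  expect_identical(r$predicted_class, "A")
  # identical pixels return their own vector; order never matters
  same <- matrix(rep(c(0.3, 0.5, 0.2), 4), 4, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(unname(average_vote(same)$class_confidence[[1]]),
               c(0.3, 0.5, 0.2))
})

test_that("all strategies are invariant to pixel ordering", {
  withr::with_seed(9, {
    p <- random_simplex(15, 4)
    perm <- sample(15)
    for (f in list(majority_vote, average_vote,
                   function(x) bayesian_vote(x, alpha = 0.35))) {
      expect_equal(f(p)$class_confidence[[1]],
                   f(p[perm, , drop = FALSE])$class_confidence[[1]])
    }
  })
})

test_that("single-pixel Bayesian aggregation reproduces the pixel", {
  p <- matrix(c(0.15, 0.6, 0.25), 1, dimnames = list(NULL, c("A", "B", "C")))
  r <- bayesian_vote(p, alpha = 1)
  expect_equal(unname(r$class_confidence[[1]]), as.vector(p),
               tolerance = 1e-12)
  expect_identical(r$predicted_class, "B")
})

test_that("Bayesian aggregation equals the brute-force odds-product posterior", {
  withr::with_seed(10, {
    worst <- 0
    for (rep in 1:1000) {
      n <- sample(1:10, 1)
      pa <- runif(n, 0.01, 0.99)
      p <- cbind(A = pa, B = 1 - pa)
      got <- bayesian_vote(p, alpha = 1)$class_confidence[[1]][["A"]]
      want <- odds_product_posterior(pa)
      worst <- max(worst, abs(got - want))
    }
    expect_lt(worst, 1e-9)
  })
})

test_that("duplicating every pixel doubles I(k) but keeps the class", {
  withr::with_seed(12, {
    p <- random_simplex(6, 3)
    r1 <- bayesian_vote(p)
    r2 <- bayesian_vote(rbind(p, p))
    expect_identical(r2$predicted_class, r1$predicted_class)
    # log-odds of the duplicated field are exactly doubled
    # recover I(k) from the confidences; saturation near 1 limits precision
    i1 <- stats::qlogis(1 - r1$class_confidence[[1]])
    i2 <- stats::qlogis(1 - r2$class_confidence[[1]])
    expect_equal(i2, 2 * i1, tolerance = 1e-5)
  })
})

test_that("adding a positive binary pixel never decreases Bayesian confidence", {
  withr::with_seed(13, {
    for (rep in 1:30) {
      pa <- runif(sample(1:8, 1), 0.05, 0.95)
      extra <- runif(1, 0.5 + 1e-6, 0.999)
      before <- bayesian_vote(cbind(A = pa, B = 1 - pa))
      after <- bayesian_vote(cbind(A = c(pa, extra), B = 1 - c(pa, extra)))
      expect_gte(after$class_confidence[[1]][["A"]],
                 before$class_confidence[[1]][["A"]])
    }
  })
})

test_that("hard 0/1 probabilities stay finite through eps clipping", {
  p <- rbind(c(1, 0), c(1, 0), c(0, 1))
  colnames(p) <- c("A", "B")
  r <- bayesian_vote(p)
  expect_true(all(is.finite(r$class_confidence[[1]])))
  expect_identical(r$predicted_class, "A")
  expect_error(bayesian_vote(p, eps = 0.7), "eps")
  expect_error(bayesian_vote(matrix(c(NaN, 1), 1)), "finite|sum")
})

test_that("confident minority pixels can flip Bayesian against majority", {
  p <- rbind(matrix(rep(c(0.55, 0.45), 3), 3, byrow = TRUE),
             matrix(rep(c(0.01, 0.99), 2), 2, byrow = TRUE))
  colnames(p) <- c("A", "B")
  expect_identical(majority_vote(p)$predicted_class, "A")
  expect_identical(bayesian_vote(p)$predicted_class, "B")
})

test_that("renormalized Bayesian confidences form a distribution", {
  withr::with_seed(14, {
    p <- random_simplex(9, 4)
    r <- bayesian_vote(p, renormalize = TRUE)
    expect_equal(sum(r$class_confidence[[1]]), 1, tolerance = 1e-12)
    expect_identical(r$predicted_class, bayesian_vote(p)$predicted_class)
  })
})

test_that("field-map aggregation dispatches per labeled field", {
  fm <- make_two_fields(h = 4, w = 6)
  classes <- c("Grass", "Maize")
  probs <- array(0, c(4, 6, 2), dimnames = list(NULL, NULL, classes))
  # field 1 pixels favor Maize, field 2 favors Grass
  probs[, , "Maize"] <- 0.8; probs[, , "Grass"] <- 0.2
  probs[, 5:6, "Maize"] <- 0.1; probs[, 5:6, "Grass"] <- 0.9
  # background gets uniform
  probs[, 3:4, ] <- 0.5

  for (m in c("majority", "average", "bayesian")) {
    res <- aggregate_field_map(probs, fm, method = m)
    expect_equal(nrow(res), 2)
    expect_identical(res$predicted_class, c("Maize", "Grass"))
  }
  expect_error(aggregate_field_map(probs[1:3, , ], fm), "aligned")
})

test_that("fields with no usable pixels are flagged, not forced", {
  fm <- make_two_fields(h = 4, w = 6)
  probs <- array(0.5, c(4, 6, 2), dimnames = list(NULL, NULL, c("A", "B")))
  mask <- matrix(TRUE, 4, 6)
  mask[, 1:2] <- FALSE  # kill all of field 1
  res <- aggregate_field_map(probs, fm, method = "average",
                             valid_mask = mask)
  expect_true(is.na(res$predicted_class[res$field_id == 1]))
  expect_equal(res$n_pixels[res$field_id == 1], 0L)
  expect_false(is.na(res$predicted_class[res$field_id == 2]))
})

test_that("aggregate_pixels matches aggregate_field_map on the same data", {
  fm <- make_two_fields(h = 5, w = 8)
  classes <- c("A", "B", "C")
  withr::with_seed(15, {
    probs <- array(random_simplex(40, 3), c(5, 8, 3),
                   dimnames = list(NULL, NULL, classes))
  })
  flat <- matrix(probs, 40, 3, dimnames = list(NULL, classes))
  ids <- as.vector(fm$field_ids)
  for (m in c("majority", "average", "bayesian")) {
    a <- aggregate_field_map(probs, fm, method = m)
    b <- aggregate_pixels(flat, ids, method = m)
    expect_equal(a$predicted_class, b$predicted_class)
    expect_equal(a$confidence, b$confidence)
  }
})

test_that("alpha grid search reports accuracy per candidate", {
  fm <- make_two_fields(h = 4, w = 6, classes = c("A", "B"))
  probs <- array(0, c(4, 6, 2), dimnames = list(NULL, NULL, c("A", "B")))
  probs[, , "A"] <- 0.7; probs[, , "B"] <- 0.3
  probs[, 5:6, "A"] <- 0.2; probs[, 5:6, "B"] <- 0.8
  # alpha must stay above 1/N (here 0.5) for smoothing to preserve ranks
  out <- tune_alpha(probs, fm, alphas = c(0.7, 1))
  expect_equal(nrow(out), 2)
  expect_equal(out$overall_accuracy, c(100, 100))
})

test_that("tidiers expose long confidences and run summaries", {
  p <- random_simplex(10, 3, seed = 20)
  res <- aggregate_pixels(p, rep(1:2, 5), method = "bayesian", alpha = 0.35)
  long <- tidy(res)
  expect_equal(nrow(long), 6)  # 2 fields x 3 classes
  expect_setequal(unique(long$class), c("A", "B", "C"))
  g <- glance(res)
  expect_identical(g$method, "bayesian")
  expect_equal(g$n_fields, 2)
})
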