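test_that("metric identities hold at the extremes", {
  y <- c(1, 1, 0, 0)
  perfect <- c(1, 1, 0, 0)
  expect_equal(misclassification_error(perfect, y), 0)
  expect_equal(gbs(perfect, y), 0)
  expect_equal(bcm(perfect, y), 1)
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), y), 1)

  wrong <- 1 - perfect
  expect_equal(misclassification_error(wrong, y), 1)
  expect_equal(gbs(wrong, y), 1)
  expect_equal(bcm(wrong, y), 0)

  flat <- rep(0.5, 4)
  expect_equal(gbs(flat, y), 0.25)
  expect_equal(bcm(flat, y), 0.5)
})

test_that("metrics match hand-computed worked examples", {
  expect_equal(gbs(c(0.9, 0.2), c(1, 0)), 0.025)
  expect_equal(bcm(c(0.9, 0.2), c(1, 0)), 0.85)
  expect_equal(misclassification_error(c(0.6, 0.4, 0.7), c(1, 1, 0)), 2 / 3)
  # positives ranked 1st and 3rd of 4: precision points 1 and 2/3
  expect_equal(aupr(c(0.9, 0.7, 0.5, 0.3), c(1, 0, 1, 0)), 5 / 6)
})

test_that("aupr of random scores approximates the prevalence", {
  means <- vapply(1:100, function(s) {
    set.seed(s)
    y <- rbinom(200, 1, 0.3)
    if (sum(y) == 0) return(NA_real_)
    aupr(runif(200), y)
  }, numeric(1))
  expect_lt(abs(mean(means, na.rm = TRUE) - 0.3), 0.05)
})

test_that("error and aupr are invariant to suitable monotone transforms", {
  set.seed(12)
  p <- runif(30)
  y <- rbinom(30, 1, p)
  y[1:2] <- c(0, 1)  # both classes guaranteed
  # cubing preserves order everywhere and maps [0,1] to [0,1], but moves the
  # 0.5 crossing, so only aupr must be unchanged
  expect_equal(aupr(p^3, y), aupr(p, y))
  # an affine squeeze around 0.5 preserves the crossing: error unchanged
  squeeze <- 0.5 + (p - 0.5) * 0.4
  expect_equal(misclassification_error(squeeze, y), misclassification_error(p, y))
})

test_that("posterior averaging is the available-case mean", {
  probs <- rbind(a = c(0.2, 0.4, 0.6), b = c(0.2, NA, 0.6), c = rep(0.5, 3))
  avg <- average_posteriors(probs)
  expect_equal(unname(avg), c(0.4, 0.4, 0.5))
  probs2 <- rbind(a = c(0.2, 0.3), b = c(NA_real_, NA_real_))
  expect_warning(avg2 <- average_posteriors(probs2), "dropped")
  expect_named(avg2, "a")
})

test_that("per-timepoint classifiers separate a separable toy and calibrate", {
  ds <- make_eset(G = 2, n1 = 8, n0 = 8, T = 2, seed = 81, sd = 0.2)
  for (t in 1:2) ds <- add_mean_shift(ds, 1, t, 20)
  features <- tibble::tibble(gene_id = rep(ds$gene_ids[1], 2), time_index = 1:2)
  clf <- fit_timepoint_classifiers(ds, features)
  post <- average_posteriors(predict_posteriors(clf, ds))
  expect_true(all(post[ds$labels == 1] > 0.5))
  expect_true(all(post[ds$labels == 0] < 0.5))
  # determinism: refitting on the same data gives identical posteriors
  clf2 <- fit_timepoint_classifiers(ds, features)
  expect_identical(predict_posteriors(clf2, ds), predict_posteriors(clf, ds))
})

test_that("time points without features contribute a flat 0.5 posterior", {
  ds <- make_eset(G = 2, n1 = 5, n0 = 5, T = 2, seed = 83)
  features <- tibble::tibble(gene_id = ds$gene_ids[1], time_index = 1L)
  clf <- fit_timepoint_classifiers(ds, features)
  probs <- predict_posteriors(clf, ds)
  expect_true(all(probs[, 2] == 0.5))
})

test_that("degenerate single-class training slices are rejected", {
  ds <- make_eset(G = 2, n1 = 5, n0 = 5, T = 2, seed = 85)
  # knock out all control measurements of the feature gene at time 1
  ds$mask[1, ds$labels == 0, 1] <- FALSE
  features <- tibble::tibble(gene_id = ds$gene_ids[1], time_index = 1L)
  expect_error(fit_timepoint_classifiers(ds, features),
               class = "longsamgsr_insufficient_data_error")
})

test_that("evaluate_features composes fitting, scoring and the four metrics", {
  train <- make_eset(G = 5, n1 = 10, n0 = 10, T = 3, seed = 87, sd = 0.5)
  test <- make_eset(G = 5, n1 = 8, n0 = 8, T = 3, seed = 88, sd = 0.5)
  for (t in 1:3) {
    train <- add_mean_shift(train, 1, t, 6)
    test <- add_mean_shift(test, 1, t, 6)
  }
  features <- tibble::tibble(gene_id = rep(train$gene_ids[1], 3), time_index = 1:3)
  rep <- evaluate_features(train, test, features)
  m <- glance(rep)
  expect_named(m, c("error", "gbs", "bcm", "aupr"))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m$error, 0)
  expect_equal(m$aupr, 1)
  td <- tidy(rep)
  expect_equal(td$optimum, c(0, 0, 1, 1))
})
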