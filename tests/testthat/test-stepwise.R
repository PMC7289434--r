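test_that("split drawing is deterministic and guards the span", {
  fm <- planted_matrix(2000, seed = 1, span_days = 250)
  s1 <- make_splits(fm, R = 20, seed = 42)
  s2 <- make_splits(fm, R = 20, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1, 20L)
  for (sp in s1) {
    expect_equal(as.numeric(sp$train_end - sp$train_start), 182)
    expect_equal(sp$test_start, sp$train_end)  # test immediately follows train
    expect_equal(as.numeric(sp$test_end - sp$test_start), 14)
  }
  short <- planted_matrix(300, seed = 2, span_days = 150)
  expect_error(make_splits(short, R = 5, seed = 1), "196")
})

test_that("a single-candidate pool forces the choice", {
  fm <- planted_matrix(200, p = 3, seed = 3)
  path <- forward_stepwise(fm, fm, n_max = 5, folds = 5, seed = 1,
                           candidates = "f2")
  expect_equal(path$features, "f2")
})

test_that("the planted linear driver is found first, repeatedly", {
  firsts <- vapply(1:20, function(r) {
    fm <- planted_matrix(400, p = 10, beta = c(f1 = 2), noise_sd = 1,
                         seed = 100 + r)
    forward_stepwise(fm, fm, n_max = 3, folds = 10, seed = r)$features[1L]
  }, character(1))
  expect_gte(sum(firsts == "f1"), 19L)  # >= 95% of replicates
})

test_that("the first selection agrees with an exhaustive single-feature scan", {
  fm <- planted_matrix(300, p = 8, beta = c(f1 = 0.4, f5 = 0.5),
                       noise_sd = 2, seed = 9)
  n <- nrow(fm)
  folds <- 5
  fold <- withr::with_seed(77, sample(rep(seq_len(folds), length.out = n)))
  # independent oracle: lm per fold per candidate
  cand <- paste0("f", 1:8)
  cv <- vapply(cand, function(f) {
    sse <- 0
    for (k in seq_len(folds)) {
      tr <- fm[fold != k, ]; te <- fm[fold == k, ]
      fit <- lm(stats::reformulate(f, "target"), data = tr)
      sse <- sse + sum((te$target - predict(fit, te))^2)
    }
    sse / n
  }, numeric(1))
  path <- forward_stepwise(fm, fm, n_max = 1, folds = folds, seed = 77)
  expect_equal(path$features[1L], names(which.min(cv)))
  expect_equal(unname(path$cv_mse[1L]), unname(min(cv)), tolerance = 1e-8)
})

test_that("paths honour length, uniqueness and near-monotone CV error", {
  fm <- planted_matrix(600, p = 25, beta = c(f1 = 2, f2 = 1, f3 = 0.5),
                       seed = 4)
  path <- forward_stepwise(fm, fm, n_max = 20, folds = 10, seed = 5)
  expect_length(path$features, 20L)
  expect_false(anyDuplicated(path$features) > 0)
  # strictly decreasing while real signal is being added
  expect_true(all(diff(path$cv_mse[1:3]) < 0))
  # and never more than marginally increasing afterwards
  expect_true(all(diff(path$cv_mse) <= 0.02 * path$cv_mse[-length(path$cv_mse)]))
})

test_that("degenerate training inputs are rejected", {
  fm <- planted_matrix(50, p = 3, seed = 6)
  fm$target <- 7
  expect_error(forward_stepwise(fm, fm, n_max = 2, folds = 5, seed = 1),
               "constant target")
  tiny <- planted_matrix(4, p = 3, seed = 6)
  expect_error(forward_stepwise(tiny, tiny, n_max = 2, folds = 10, seed = 1),
               "folds")
})

test_that("the error curve is anchored at 100% for the intercept-only model", {
  train <- planted_matrix(400, p = 6, seed = 8)
  test <- planted_matrix(150, p = 6, seed = 18)
  path <- forward_stepwise(train, test, n_max = 5, folds = 5, seed = 2)
  curve <- testing_percentage_error(path, test)
  expect_equal(curve$pct_error[curve$n_features == 0], 100)
  expect_lt(curve$pct_error[curve$n_features == 1], 100)  # planted signal helps

  # a perfect linear model reaches 0%
  exact <- planted_matrix(200, p = 4, beta = c(f1 = 3), noise_sd = 0, seed = 10)
  p2 <- forward_stepwise(exact, exact, n_max = 1, folds = 5, seed = 3)
  expect_equal(p2$pct_error[2], 0, tolerance = 1e-10)

  p3 <- forward_stepwise(exact, exact, n_max = 1, folds = 5, seed = 3)
  const <- exact
  const$target <- p3$train_mean  # test target == intercept prediction
  expect_error(testing_percentage_error(p3, const), "zero")
})

test_that("selection frequencies count appearances with stated tie-breaks", {
  fm <- planted_matrix(300, p = 6, beta = c(f1 = 2), seed = 11)
  paths <- lapply(1:4, function(r) {
    forward_stepwise(fm, fm, n_max = 3, folds = 5, seed = r)
  })
  sf <- selection_frequency(paths, k = 3)
  expect_equal(attr(sf, "R"), 4L)
  f1row <- sf[sf$feature == "f1", ]
  expect_equal(f1row$count, 4)
  expect_equal(f1row$frequency_pct, 100)
  expect_equal(sf$feature[1L], "f1")  # rank 1
  expect_true(all(sf$count <= 4 & sf$count >= 0))

  # hand-built tie: equal counts broken by mean step, then name
  p_a <- list(features = c("x", "y"))
  p_b <- list(features = c("y", "x"))
  p_c <- list(features = c("x", "z"))
  sf2 <- selection_frequency(list(p_a, p_b, p_c), k = 2)
  expect_equal(sf2$feature, c("x", "y", "z"))  # x: mean step (1+2+1)/3 < y's
  expect_error(selection_frequency(list()), "no paths")
})

test_that("feature-set evaluation returns test MAE in minutes", {
  exact <- planted_matrix(120, p = 4, beta = c(f2 = 3), noise_sd = 0, seed = 12)
  expect_equal(evaluate_feature_set("f2", exact, exact), 0, tolerance = 1e-10)

  # intercept-only on test targets {0, 10} with train mean 5 -> MAE 5
  train <- planted_matrix(40, p = 2, seed = 13)
  train$target <- 5
  test <- planted_matrix(2, p = 2, seed = 14)
  test$target <- c(0, 10)
  train$f1 <- 0; test$f1 <- 0  # constant feature: model = intercept = mean
  expect_equal(evaluate_feature_set("f1", train, test), 5)

  expect_error(evaluate_feature_set("nope", train, test), "unknown feature")
})
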