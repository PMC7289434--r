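test_that("set algebra: union, intersection, idempotence", {
  a <- feature_set(c("LineCount0", "SumWaits"), "a")
  b <- feature_set(c("SumWaits", "AheadCount"), "b")
  expect_equal(as.character(union_sets(list(a, b))),
               c("LineCount0", "SumWaits", "AheadCount"))
  expect_equal(as.character(union_sets(list(a, a))), as.character(a))
  expect_equal(as.character(intersect_sets(a, b)), "SumWaits")
  expect_equal(as.character(intersect_sets(a, a)), as.character(a))
  expect_length(intersect_sets(a, feature_set("Median5", "c")), 0L)
  expect_warning(feature_set(c("LineCount0", "NotAFeature"), "x"),
                 "unresolved")
})

test_that("the published LR and RF unions share exactly the eight features", {
  sets <- published_feature_sets()
  expect_length(sets$lr_union, 17L)
  expect_length(sets$rf_union, 14L)
  common <- intersect_sets(sets$lr_union, sets$rf_union)
  expect_length(common, 8L)
  expect_setequal(as.character(common),
                  c("LineCount0Strict", "AheadCount", "StartTime4",
                    "NumCompletedToday", "DelayedInLine", "SumWaits",
                    "SumDelayInProgress", "BeforeSlot"))
})

test_that("walk-in applicability filtering reproduces the published counts", {
  sets <- published_feature_sets()
  # RF union: only the delay-defined features drop -> 12 remain
  rf_app <- applicable_subset(sets$rf_union, "walkin")
  expect_length(rf_app, 12L)
  expect_false(any(c("DelayedInLine", "DelayCount") %in% as.character(rf_app)))
  # strict filtering also drops schedule-grid features: LR union 17 -> 8
  lr_strict <- applicable_subset(sets$lr_union, "walkin", strict = TRUE)
  expect_length(lr_strict, 8L)
  expect_setequal(as.character(lr_strict),
                  c("AheadCount", "StartTime4", "InProgressSize",
                    "NumCompletedToday", "LineCount0", "AvgWaitForDay",
                    "SumWaits", "SumDelayInProgress"))
  # scheduled facilities keep everything
  expect_equal(as.character(applicable_subset(sets$lr_union, "scheduled")),
               as.character(sets$lr_union))
  expect_length(applicable_subset(feature_set(character(0), "e"), "walkin"), 0L)
})

test_that("transfer of the identical set has ratio exactly 1", {
  fm <- planted_matrix(1500, p = 8, beta = c(f1 = 2, f2 = 1), seed = 50,
                       span_days = 220)
  splits <- make_splits(fm, R = 4, seed = 7, train_days = 60, test_days = 10)
  s <- fs(c("f1", "f2"), "s")
  tr <- transfer_ratio(fm, s, s, "linear", splits)
  expect_identical(tr$ratio, 1)
  expect_identical(unname(tr$ci), c(1, 1))
  # forests too: same features + same per-split seed -> identical fits
  trf <- transfer_ratio(fm, s, s, "forest", splits,
                        params = rf_params(1, 8, 50))
  expect_identical(trf$ratio, 1)
})

test_that("a pure-noise transferred set is worse than the true drivers", {
  fm <- planted_matrix(1500, p = 8, beta = c(f1 = 3, f2 = 2), noise_sd = 1,
                       seed = 51, span_days = 220)
  splits <- make_splits(fm, R = 4, seed = 8, train_days = 60, test_days = 10)
  tr <- transfer_ratio(fm, fs(c("f7", "f8"), "noise"),
                       fs(c("f1", "f2"), "true"), "linear", splits)
  expect_gt(tr$ratio, 1)
  expect_error(
    transfer_ratio(fm, fs("zz", "empty"),
                   fs("f1", "true"), "linear", splits),
    "empty feature set")
})

test_that("cross-model transfer fills a 2x2 MAE table", {
  fm <- planted_matrix(1200, p = 6, beta = c(f1 = 2), seed = 52,
                       span_days = 220)
  splits <- make_splits(fm, R = 2, seed = 9, train_days = 60, test_days = 10)
  out <- cross_model_transfer(fm, fs(c("f1", "f2"), "lr"),
                              fs(c("f1", "f3"), "rf"), splits,
                              params = rf_params(1, 8, 60))
  expect_equal(dim(out), c(2L, 2L))
  expect_true(all(out > 0))
  # identical sets give identical columns
  same <- cross_model_transfer(fm, fs("f1", "a"),
                               fs("f1", "b"), splits,
                               params = rf_params(1, 8, 60))
  expect_equal(same[, "lr_set"], same[, "rf_set"])
})
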