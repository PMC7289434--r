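#' Draw replicate train/test splits
#'
#' The repeated-selection protocol resamples, for each replicate, a random
#' consecutive training window of visits followed immediately by a consecutive
#' test window.  Window starts are drawn uniformly over admissible days
#' (overlapping windows across replicates are allowed); everything is
#' deterministic given `seed`.
#'
#' @param matrix a `feature_matrix` (needs the `prediction_time` column).
#' @param R number of replicates.
#' @param seed integer seed.
#' @param train_days,test_days window lengths in days.  Defaults are the
#'   published protocol: six months (182 days) of training visits and the
#'   following two weeks (14 days) of test visits.
#' @return List of `R` split specifications: `replicate`, `train_start`,
#'   `train_end`, `test_start`, `test_end` (Dates, end-exclusive) and a
#'   per-replicate `seed`.
#' @export
make_splits <- function(matrix, R, seed, train_days = 182, test_days = 14) {
  stopifnot(is_count(R))
  days <- ts_day(matrix$prediction_time)
  span <- as.numeric(max(days) - min(days)) + 1
  need <- train_days + test_days
  if (span < need) {
    stopf("make_splits: log spans %d days but %d (train %d + test %d) are required",
          span, need, train_days, test_days)
  }
  first <- min(days)
  n_starts <- span - need + 1
  withr::with_seed(seed, {
    starts <- first + (sample.int(n_starts, R, replace = TRUE) - 1L)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, R)
    lapply(seq_len(R), function(r) {
      s <- starts[r]
      structure(list(
        replicate = r,
        train_start = s, train_end = s + train_days,
        test_start = s + train_days, test_end = s + train_days + test_days,
        seed = sub_seeds[r]
      ), class = "split_spec")
    })
  })
}

#' Materialize one split as train/test row sets
#'
#' @param matrix a `feature_matrix`.
#' @param split one element of [make_splits()].
#' @return List with `train` and `test` data.frames.
#' @export
split_matrix <- function(matrix, split) {
  days <- ts_day(matrix$prediction_time)
  list(
    train = matrix[days >= split$train_start & days < split$train_end, , drop = FALSE],
    test = matrix[days >= split$test_start & days < split$test_end, , drop = FALSE]
  )
}

#' Forward stepwise linear-regression selection
#'
#' At each step, every remaining candidate feature is appended in turn to the
#' current ordinary-least-squares model and scored by 10-fold cross-validated
#' MSE on the training set; the candidate with the lowest CV-MSE is added
#' (ties broken by catalog order).  Exactly `n_max` features are added.  For
#' every model size `N = 0..n_max` the model is refitted on the full training
#' set and its test-set MSE recorded, from which the Testing Percentage Error
#' curve is derived (`100 * testMSE(N) / testMSE(intercept-only)`; the
#' intercept-only prediction is the training-set mean target).
#'
#' @param train,test feature matrices (train rows `>= folds`).
#' @param n_max number of features to add.
#' @param folds number of cross-validation folds.
#' @param seed seed for the random fold assignment.
#' @param candidates optional character vector restricting the candidate pool
#'   (default: all feature columns).
#' @return A `stepwise_path`: `features` (ordered selections), `cv_mse`
#'   (CV-MSE after each addition), `test_mse` and `pct_error` (Testing
#'   Percentage Error) for sizes `0..n_max`, plus the fitted coefficients per
#'   size.
#' @export
forward_stepwise <- function(train, test, n_max = 20, folds = 10, seed = 1L,
                             candidates = NULL) {
  feats <- candidates %||% feature_names(train)
  stopifnot(all(feats %in% names(train)))
  y <- train$target
  n <- length(y)
  if (n < folds) stopf("forward_stepwise: %d training rows < %d folds", n, folds)
  if (stats::sd(y) == 0) stopf("forward_stepwise: constant target in training set")
  n_max <- min(n_max, length(feats))

  X <- as.matrix(train[feats])
  spec <- scale_spec(X)
  Xs <- apply_scale(X, spec)
  X1 <- cbind(1, Xs)

  fold <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  g <- gram_folds(X1, y, fold)

  p <- length(feats)
  selected <- integer(0)
  cv_path <- numeric(n_max)
  for (step in seq_len(n_max)) {
    remaining <- setdiff(seq_len(p), selected)
    scores <- vapply(remaining, function(j) {
      cv_mse_for(g, c(1L, selected + 1L, j + 1L))
    }, numeric(1))
    best <- remaining[which.min(scores)]  # which.min: first minimum = catalog order
    selected <- c(selected, best)
    cv_path[step] <- min(scores)
  }

  # refit each model size on the full training set
  train_mean <- mean(y)
  coefs <- vector("list", n_max + 1L)
  coefs[[1L]] <- train_mean
  for (k in seq_len(n_max)) {
    S <- c(1L, selected[seq_len(k)] + 1L)
    beta <- psd_solve(g$A[S, S, drop = FALSE], g$b[S])
    coefs[[k + 1L]] <- stats::setNames(beta, colnames(X1)[S] %||% NULL)
  }

  path <- structure(list(
    features = feats[selected],
    feature_idx = selected,
    cv_mse = cv_path,
    coefs = coefs,
    scale = spec,
    feats = feats,
    train_mean = train_mean,
    n_max = n_max, folds = folds, seed = seed
  ), class = "stepwise_path")

  curve <- testing_percentage_error(path, test)
  path$test_mse <- curve$test_mse
  path$pct_error <- curve$pct_error
  path
}

#' @export
print.stepwise_path <- function(x, ...) {
  cat(sprintf("<stepwise_path> %d features added; first 5: %s\n", x$n_max,
              paste(utils::head(x$features, 5L), collapse = ", ")))
  if (!is.null(x$pct_error)) {
    cat(sprintf("  Testing Percentage Error: 100%% (N=0) -> %.1f%% (N=%d)\n",
                x$pct_error[length(x$pct_error)], x$n_max))
  }
  invisible(x)
}

# Internal: predictions of the size-k model of a path on new rows.
path_predict <- function(path, newdata, k) {
  if (k == 0L) return(rep(path$train_mean, nrow(newdata)))
  sel <- path$feature_idx[seq_len(k)]
  Xs <- apply_scale(as.matrix(newdata[path$feats]), path$scale)
  drop(cbind(1, Xs[, sel, drop = FALSE]) %*% path$coefs[[k + 1L]])
}

#' Testing Percentage Error curve
#'
#' For each model size `N` along a stepwise path, the ratio of the test MSE of
#' the size-`N` model to the test MSE of the intercept-only model, expressed
#' as a percentage.  `N = 0` is the intercept-only model and therefore exactly
#' 100%.
#'
#' @param path a [forward_stepwise()] result.
#' @param test feature matrix to evaluate on.
#' @return data.frame with columns `n_features`, `test_mse`, `pct_error`.
#' @export
testing_percentage_error <- function(path, test) {
  stopifnot(inherits(path, "stepwise_path"))
  y <- test$target
  mse <- vapply(0:path$n_max, function(k) {
    mean((y - path_predict(path, test, k))^2)
  }, numeric(1))
  if (mse[1L] == 0) {
    stopf("testing_percentage_error: intercept-only test MSE is zero")
  }
  data.frame(n_features = 0:path$n_max, test_mse = mse,
             pct_error = 100 * mse / mse[1L])
}

#' Cross-replicate selection frequencies
#'
#' Counts, over a list of stepwise paths, how often each feature entered the
#' model, and extracts the top-`k` features by frequency (ties broken by mean
#' selection step — earlier is better — then by name).
#'
#' @param paths list of [forward_stepwise()] results.
#' @param k size of the reduced feature set (default 10).
#' @return A `selection_summary`: data.frame `feature`, `count`,
#'   `frequency_pct`, `mean_step`, sorted by the ranking rule, with attributes
#'   `top` (the top-`k` names) and `R` (replicate count).
#' @export
selection_frequency <- function(paths, k = 10) {
  if (!length(paths)) stopf("selection_frequency: no paths supplied")
  R <- length(paths)
  tab <- list()
  for (path in paths) {
    for (s in seq_along(path$features)) {
      f <- path$features[s]
      cur <- tab[[f]] %||% c(count = 0, steps = 0)
      tab[[f]] <- c(count = cur[["count"]] + 1, steps = cur[["steps"]] + s)
    }
  }
  df <- data.frame(
    feature = names(tab),
    count = vapply(tab, `[[`, numeric(1), "count"),
    mean_step = vapply(tab, function(x) x[["steps"]] / x[["count"]], numeric(1)),
    stringsAsFactors = FALSE
  )
  df$frequency_pct <- 100 * df$count / R
  df <- df[order(-df$count, df$mean_step, df$feature), ]
  rownames(df) <- NULL
  structure(df[c("feature", "count", "frequency_pct", "mean_step")],
            top = utils::head(df$feature, k), R = R, k = k,
            class = c("selection_summary", "data.frame"))
}

#' Top-k features of a selection summary
#' @param summary a [selection_frequency()] result.
#' @return Character vector of the top-`k` feature names.
#' @export
top_features <- function(summary) attr(summary, "top")

#' Fit a feature set and measure its test error
#'
#' @param features character vector of feature names (all must exist in the
#'   matrices).
#' @param train,test feature matrices.
#' @param model `"linear"` (OLS) or `"forest"` (random forest via ranger).
#' @param params optional [rf_params()] for forest models.
#' @param seed seed for forest fitting.
#' @return Mean absolute error on the test set, in minutes.
#' @export
evaluate_feature_set <- function(features, train, test,
                                 model = c("linear", "forest"),
                                 params = NULL, seed = 1L) {
  model <- match.arg(model)
  unknown <- setdiff(features, names(train))
  if (length(unknown)) {
    stopf("evaluate_feature_set: unknown feature(s): %s",
          paste(unknown, collapse = ", "))
  }
  if (!length(features)) stopf("evaluate_feature_set: empty feature set")
  if (model == "linear") {
    coef <- ols_fit(train[features], train$target)
    pred <- ols_predict(coef, test[features])
  } else {
    fit <- fit_forest(train, features, params, seed)
    pred <- stats::predict(fit, data = test[features])$predictions
  }
  mean(abs(test$target - pred))
}

#' Run the full repeated stepwise-selection protocol
#'
#' Convenience wrapper: draws `R` train/test splits, runs [forward_stepwise()]
#' on each, and summarizes cross-replicate selection frequencies.
#'
#' @inheritParams make_splits
#' @param n_max,folds passed to [forward_stepwise()].
#' @param k reduced-set size for [selection_frequency()].
#' @return List with `paths`, `summary` (a [selection_frequency()] result) and
#'   `splits`.
#' @export
run_stepwise_selection <- function(matrix, R = 100, n_max = 20, folds = 10,
                                   seed = 1L, k = 10,
                                   train_days = 182, test_days = 14) {
  splits <- make_splits(matrix, R, seed, train_days, test_days)
  paths <- lapply(splits, function(sp) {
    parts <- split_matrix(matrix, sp)
    forward_stepwise(parts$train, parts$test, n_max = n_max, folds = folds,
                     seed = sp$seed)
  })
  list(paths = paths, summary = selection_frequency(paths, k), splits = splits)
}
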