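#' Random-forest hyperparameters
#'
#' @param mtry variables considered at each split.
#' @param max_depth maximum tree depth; `0` means unlimited.
#' @param num_trees trees per forest.
#' @return An `rf_params` list.
#' @export
rf_params <- function(mtry, max_depth = 0L, num_trees = 500L) {
  stopifnot(is_count(mtry), is_count(num_trees),
            is.numeric(max_depth), max_depth >= 0)
  structure(list(mtry = as.integer(mtry), max_depth = as.integer(max_depth),
                 num_trees = as.integer(num_trees)), class = "rf_params")
}

#' Default hyperparameter tuning grid
#'
#' Variables-per-split in `{p/3, sqrt(p), p/2}` (floored, deduplicated), depth
#' in `{8, 16, unlimited}` and `{200, 500}` trees.
#'
#' @param p number of candidate features.
#' @return List of [rf_params()] grid points.
#' @export
default_rf_grid <- function(p) {
  mtrys <- unique(pmax(1L, c(p %/% 3L, floor(sqrt(p)), p %/% 2L)))
  grid <- list()
  for (m in mtrys) for (d in c(8L, 16L, 0L)) for (tr in c(200L, 500L)) {
    grid[[length(grid) + 1L]] <- rf_params(m, d, tr)
  }
  grid
}

fit_forest <- function(train, features, params = NULL, seed = 1L,
                       importance = "none") {
  params <- params %||% rf_params(max(1L, floor(length(features) / 3)))
  mtry <- min(params$mtry, length(features))
  dat <- data.frame(train[features], target = train$target,
                    check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = "target", data = dat,
    num.trees = params$num_trees,
    mtry = mtry,
    max.depth = params$max_depth,
    importance = importance,
    seed = seed, num.threads = 1L,
    respect.unordered.factors = FALSE
  )
}

#' Tune random-forest hyperparameters by cross-validation
#'
#' Scores every grid point by `folds`-fold cross-validated MSE on the training
#' set and returns the best (ties: first grid point).  Deterministic given
#' `seed`.
#'
#' @param train feature matrix.
#' @param grid list of [rf_params()]; see [default_rf_grid()].
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment and forest fitting).
#' @param features optional candidate restriction.
#' @return The winning `rf_params`, with attributes `cv_mse` (vector over the
#'   grid) and `grid`.
#' @export
tune_rf <- function(train, grid = default_rf_grid(length(feature_names(train))),
                    folds = 10, seed = 1L, features = NULL) {
  if (!length(grid)) stopf("tune_rf: empty hyperparameter grid")
  features <- features %||% feature_names(train)
  n <- nrow(train)
  fold <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv <- vapply(seq_along(grid), function(gi) {
    params <- grid[[gi]]
    sse <- 0
    for (f in seq_len(folds)) {
      idx <- fold == f
      fit <- fit_forest(train[!idx, , drop = FALSE], features, params,
                        seed = seed + f)
      pred <- stats::predict(fit, data = train[idx, features, drop = FALSE],
                             num.threads = 1L)$predictions
      sse <- sse + sum((train$target[idx] - pred)^2)
    }
    sse / n
  }, numeric(1))
  best <- grid[[which.min(cv)]]
  attr(best, "cv_mse") <- cv
  attr(best, "grid") <- grid
  best
}

#' Permutation importance of a fitted forest
#'
#' Fits a random forest on the training rows and scores every candidate
#' feature by its out-of-bag permutation importance: the mean increase in
#' out-of-bag MSE when the feature's values are permuted.  Negative scores are
#' kept as-is (they are an informative noise floor).
#'
#' @param train feature matrix (at least 2 rows).
#' @param test optional feature matrix; when supplied, the test-set MAE of the
#'   fitted forest is attached as attribute `test_mae`.
#' @param params [rf_params()]; a default is derived when `NULL`.
#' @param seed integer seed.
#' @param features optional candidate restriction.
#' @return Named numeric vector of importance scores (one per feature).
#' @export
rf_importance <- function(train, test = NULL, params = NULL, seed = 1L,
                          features = NULL) {
  features <- features %||% feature_names(train)
  if (nrow(train) < 2L) stopf("rf_importance: need at least 2 training rows")
  fit <- fit_forest(train, features, params, seed, importance = "permutation")
  imp <- fit$variable.importance[features]
  if (!is.null(test)) {
    pred <- stats::predict(fit, data = test[features], num.threads = 1L)$predictions
    attr(imp, "test_mae") <- mean(abs(test$target - pred))
  }
  imp
}

#' Cumulative-importance ranking across replicates
#'
#' Sums per-replicate permutation-importance scores feature-wise and ranks
#' features by the cumulative total.
#'
#' @param tables list of [rf_importance()] vectors (identical feature sets).
#' @param k size of the reduced set.
#' @return An `importance_table`: data.frame `feature`, `cumulative`,
#'   `mean_importance`, ranked, with attribute `top` (top-`k` names).
#' @export
cumulative_ranking <- function(tables, k = 10) {
  if (!length(tables)) stopf("cumulative_ranking: no replicates supplied")
  nms <- names(tables[[1L]])
  for (tb in tables) {
    if (!identical(sort(names(tb)), sort(nms))) {
      stopf("cumulative_ranking: replicates score different feature sets")
    }
  }
  cum <- Reduce(`+`, lapply(tables, function(tb) tb[nms]))
  df <- data.frame(feature = nms, cumulative = as.numeric(cum),
                   mean_importance = as.numeric(cum) / length(tables),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$cumulative, df$feature), ]
  rownames(df) <- NULL
  structure(df, top = utils::head(df$feature, k), k = k,
            R = length(tables),
            class = c("importance_table", "data.frame"))
}

#' Run the full repeated random-forest selection protocol
#'
#' Tunes hyperparameters once on the first split's training set, then fits one
#' forest per replicate split and ranks features by cumulative permutation
#' importance.
#'
#' @inheritParams make_splits
#' @param grid tuning grid (`NULL` skips tuning and uses the default params).
#' @param folds CV folds for tuning.
#' @param k reduced-set size.
#' @return List with `params`, `importances` (per replicate), `ranking` (a
#'   [cumulative_ranking()] result) and `splits`.
#' @export
run_rf_selection <- function(matrix, R = 100, seed = 1L, grid = NULL,
                             folds = 10, k = 10,
                             train_days = 182, test_days = 14) {
  splits <- make_splits(matrix, R, seed, train_days, test_days)
  first <- split_matrix(matrix, splits[[1L]])
  params <- if (is.null(grid)) {
    rf_params(max(1L, floor(length(feature_names(matrix)) / 3)))
  } else {
    tune_rf(first$train, grid, folds = folds, seed = seed)
  }
  importances <- lapply(splits, function(sp) {
    parts <- split_matrix(matrix, sp)
    rf_importance(parts$train, parts$test, params, seed = sp$seed)
  })
  list(params = params, importances = importances,
       ranking = cumulative_ranking(importances, k), splits = splits)
}
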