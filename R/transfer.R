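#' Named feature sets
#'
#' A `feature_set` is an ordered list of distinct feature names with a source
#' label (a facility id, `"union"`, or a model name).  Names are checked
#' against the catalog; names that do not resolve (e.g. legacy spellings in a
#' published list) are recorded in the `unresolved` attribute and kept.
#'
#' @param features character vector of feature names.
#' @param source single string labelling where the set came from.
#' @param catalog a [feature_catalog()] used for resolution.
#' @return A `feature_set` character vector with attributes `source` and
#'   `unresolved`.
#' @export
feature_set <- function(features, source = "set", catalog = feature_catalog()) {
  features <- as.character(features)
  features <- features[!duplicated(features)]
  unresolved <- setdiff(features, catalog$name)
  if (length(unresolved)) {
    warning(sprintf("feature_set '%s': unresolved name(s): %s", source,
                    paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  structure(features, source = source, unresolved = unresolved,
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s (%d): %s\n", attr(x, "source"), length(x),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Union of feature sets
#'
#' Distinct names ordered by first appearance across the inputs.
#'
#' @param sets list of [feature_set()]s (or character vectors).
#' @param source label for the result (default `"union"`).
#' @param catalog catalog for resolution.
#' @return A [feature_set()].
#' @export
union_sets <- function(sets, source = "union", catalog = feature_catalog()) {
  if (!length(sets)) stopf("union_sets: no sets supplied")
  all_names <- unlist(lapply(sets, as.character), use.names = FALSE)
  suppressWarnings(feature_set(all_names[!duplicated(all_names)], source, catalog))
}

#' Intersection of two feature sets
#'
#' Names present in both sets, returned in catalog order (unresolved names
#' last, in `a`'s order).
#'
#' @param a,b [feature_set()]s or character vectors.
#' @param catalog catalog defining the canonical order.
#' @return A [feature_set()].
#' @export
intersect_sets <- function(a, b, catalog = feature_catalog()) {
  common <- intersect(as.character(a), as.character(b))
  in_cat <- catalog$name[catalog$name %in% common]
  extra <- setdiff(common, in_cat)
  suppressWarnings(feature_set(
    c(in_cat, extra),
    source = sprintf("%s & %s", attr(a, "source") %||% "a",
                     attr(b, "source") %||% "b"),
    catalog))
}

#' Filter a feature set for a facility type
#'
#' Scheduled and hybrid facilities keep every feature.  For walk-in
#' facilities, features flagged `walkin_applicable = FALSE` in the catalog
#' (the delay-defined features, whose meaning collapses when every wait is
#' positive by construction) are dropped.  With `strict = TRUE`, features
#' flagged `requires_schedule` are dropped too — the conservative reading
#' under which any feature needing a real appointment grid is excluded rather
#' than computed through the arrival-as-schedule proxy.  Names that do not
#' resolve against the catalog are kept.
#'
#' @param set a [feature_set()] or character vector.
#' @param facility_type `"scheduled"`, `"hybrid"` or `"walkin"`.
#' @param catalog a [feature_catalog()].
#' @param strict also drop schedule-requiring features (walk-in only).
#' @return A [feature_set()].
#' @export
applicable_subset <- function(set, facility_type, catalog = feature_catalog(),
                              strict = FALSE) {
  facility_type <- match.arg(facility_type, FACILITY_TYPES)
  nms <- as.character(set)
  if (facility_type != "walkin") {
    return(suppressWarnings(feature_set(nms, attr(set, "source") %||% "set", catalog)))
  }
  idx <- match(nms, catalog$name)
  drop <- !is.na(idx) & !catalog$walkin_applicable[idx]
  if (strict) drop <- drop | (!is.na(idx) & catalog$requires_schedule[idx])
  suppressWarnings(feature_set(
    nms[!drop],
    source = sprintf("%s|walkin%s", attr(set, "source") %||% "set",
                     if (strict) "-strict" else ""),
    catalog))
}

#' Transfer ratio of a feature set
#'
#' Measures how much worse a *transferred* feature set predicts a facility's
#' data than the facility's own *optimal* set: over replicate train/test
#' splits, both models are fitted on the training rows and scored by test-set
#' mean absolute error; the ratio for each split is
#' `MAE(transferred) / MAE(optimal)` and the reported ratio is the mean over
#' splits.  A ratio of 1.06 means predictions with the transferred set are 6%
#' worse.  A 95% percentile interval over the replicate ratios is attached.
#'
#' @param data_matrix feature matrix of the evaluated facility.
#' @param transferred,optimal [feature_set()]s (already applicability-filtered
#'   for this facility; names must resolve in the matrix).
#' @param model `"linear"` or `"forest"`.
#' @param splits list from [make_splits()].
#' @param params optional [rf_params()] for forest models.
#' @return A `transfer_ratio` list: `ratio`, `ci` (2.5/97.5 percentiles),
#'   `per_split` ratios, `mae_transferred`, `mae_optimal`, `n_splits`.
#' @export
transfer_ratio <- function(data_matrix, transferred, optimal,
                           model = c("linear", "forest"), splits,
                           params = NULL) {
  model <- match.arg(model)
  transferred <- intersect(as.character(transferred), names(data_matrix))
  optimal <- intersect(as.character(optimal), names(data_matrix))
  if (!length(transferred) || !length(optimal)) {
    stopf("transfer_ratio: empty feature set after applicability filtering")
  }
  per <- vapply(splits, function(sp) {
    parts <- split_matrix(data_matrix, sp)
    mt <- evaluate_feature_set(transferred, parts$train, parts$test, model,
                               params = params, seed = sp$seed)
    mo <- evaluate_feature_set(optimal, parts$train, parts$test, model,
                               params = params, seed = sp$seed)
    c(mt, mo)
  }, numeric(2))
  ratios <- per[1L, ] / per[2L, ]
  structure(list(
    ratio = mean(ratios),
    ci = stats::quantile(ratios, c(0.025, 0.975), names = FALSE),
    per_split = ratios,
    mae_transferred = mean(per[1L, ]),
    mae_optimal = mean(per[2L, ]),
    n_splits = length(splits),
    model = model
  ), class = "transfer_ratio")
}

#' @export
print.transfer_ratio <- function(x, ...) {
  cat(sprintf("<transfer_ratio> %.3f (95%% CI %.2f-%.2f) over %d splits [%s]\n",
              x$ratio, x$ci[1L], x$ci[2L], x$n_splits, x$model))
  invisible(x)
}

#' Cross-facility transfer matrix
#'
#' Builds the (data facility x feature-set source) matrix of transfer ratios:
#' each facility's data is predicted with every other source's feature set and
#' compared to its own optimal set.  Diagonal cells are 1 by definition.  For
#' walk-in facilities each transferred set is first passed through
#' [applicable_subset()].
#'
#' @param matrices named list of feature matrices (one per facility).
#' @param sets named list of [feature_set()]s (same names; may include extra
#'   sources such as `"Union"`).
#' @param model `"linear"` or `"forest"`.
#' @param R replicates per cell.
#' @param seed integer seed.
#' @param catalog catalog for applicability filtering.
#' @param strict strict walk-in filtering (see [applicable_subset()]).
#' @param train_days,test_days split windows.
#' @param params optional [rf_params()].
#' @return A `transfer_matrix` list: `ratio` (numeric matrix), `ci_low`,
#'   `ci_high`, `model`.
#' @export
transfer_matrix <- function(matrices, sets, model = c("linear", "forest"),
                            R = 20, seed = 1L, catalog = feature_catalog(),
                            strict = FALSE, train_days = 182, test_days = 14,
                            params = NULL) {
  model <- match.arg(model)
  facs <- names(matrices)
  srcs <- names(sets)
  ratio <- ci_low <- ci_high <- matrix(
    NA_real_, length(facs), length(srcs), dimnames = list(facs, srcs))
  for (f in facs) {
    fm <- matrices[[f]]
    ftype <- attr(fm, "facility_type") %||% "scheduled"
    own <- applicable_subset(sets[[f]], ftype, catalog, strict)
    splits <- make_splits(fm, R, seed, train_days, test_days)
    for (s in srcs) {
      transferred <- applicable_subset(sets[[s]], ftype, catalog, strict)
      tr <- transfer_ratio(fm, transferred, own, model, splits, params)
      ratio[f, s] <- tr$ratio
      ci_low[f, s] <- tr$ci[1L]
      ci_high[f, s] <- tr$ci[2L]
    }
  }
  structure(list(ratio = ratio, ci_low = ci_low, ci_high = ci_high,
                 model = model, R = R), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> [%s, %d replicates] data facility x feature-set source\n",
              x$model, x$R))
  print(round(x$ratio, 3))
  invisible(x)
}

#' Cross-model feature transfer
#'
#' Fits each model (linear and forest) with each of two union feature sets —
#' typically the stepwise-LR union and the RF-importance union — and reports
#' test MAE, averaged over splits: a 2 x 2 table showing whether features
#' selected by one model family keep their predictive power in the other.
#'
#' @param matrix feature matrix of one facility.
#' @param lr_set,rf_set [feature_set()]s.
#' @param splits list from [make_splits()].
#' @param params optional [rf_params()].
#' @return 2 x 2 numeric matrix (rows: model; columns: feature-set source) of
#'   MAE in minutes.
#' @export
cross_model_transfer <- function(matrix, lr_set, rf_set, splits,
                                 params = NULL) {
  sets <- list(lr = intersect(as.character(lr_set), names(matrix)),
               rf = intersect(as.character(rf_set), names(matrix)))
  out <- matrix(0, 2L, 2L,
                dimnames = list(c("linear", "forest"), c("lr_set", "rf_set")))
  for (m in rownames(out)) {
    for (s in colnames(out)) {
      feats <- sets[[sub("_set", "", s)]]
      maes <- vapply(splits, function(sp) {
        parts <- split_matrix(matrix, sp)
        evaluate_feature_set(feats, parts$train, parts$test, m,
                             params = params, seed = sp$seed)
      }, numeric(1))
      out[m, s] <- mean(maes)
    }
  }
  out
}
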