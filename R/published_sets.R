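#' Published reference feature sets
#'
#' The reduced feature sets reported by the multi-facility selection study
#' that this package re-implements, shipped as data dictionaries under
#' `inst/extdata/feature_sets/`:
#' \describe{
#'   \item{`lr_union`}{Union of the per-facility top-10 sets selected by
#'     forward stepwise linear regression at the three schedule-driven
#'     facilities (17 features).}
#'   \item{`lr_f4`}{Top-10 stepwise-LR set for the walk-in facility.}
#'   \item{`rf_union`}{Union of the per-facility top-10 sets ranked by random
#'     forest cumulative permutation importance at the three schedule-driven
#'     facilities (14 features, verbatim spellings preserved).}
#'   \item{`rf_f4`}{Top-10 RF set for the walk-in facility.}
#' }
#' Two names (`AvgWaitLastK3Customers`, `NumCustomersInLast30`) are kept in
#' their published spellings even though the 84-feature catalog spells them
#' differently; they are flagged in the sets' `unresolved` attributes.
#'
#' @param catalog catalog used for name resolution.
#' @return Named list of [feature_set()]s.
#' @examples
#' sets <- published_feature_sets()
#' length(sets$lr_union)  # 17
#' length(intersect_sets(sets$lr_union, sets$rf_union))  # 8 features in common
#' @export
published_feature_sets <- function(catalog = feature_catalog()) {
  dir <- system.file("extdata", "feature_sets", package = "flowsel")
  read_one <- function(file, source) {
    df <- utils::read.csv(file.path(dir, file), stringsAsFactors = FALSE)
    suppressWarnings(feature_set(df$feature, source, catalog))
  }
  list(
    lr_union = read_one("lr_union.csv", "lr_union"),
    lr_f4 = read_one("lr_f4.csv", "lr_f4"),
    rf_union = read_one("rf_union.csv", "rf_union"),
    rf_f4 = read_one("rf_f4.csv", "rf_f4")
  )
}
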