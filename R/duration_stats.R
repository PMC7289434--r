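#' Expected service durations and facility profile
#'
#' Several catalog features need the *expected* service duration of an exam
#' code (e.g. `SumTimeToCompleteNextSlot`).  To keep the feature matrix
#' leakage-safe these expectations are frozen from a reference period that is
#' earlier than, and disjoint from, the rows being modelled: by default the
#' first `reference_days` days of the log.  The expectation is the median of
#' observed service durations per exam code, with the facility-wide median as
#' fallback for unseen codes.
#'
#' The returned profile also carries the facility metadata the feature engine
#' needs (facility type, slot grid, server count).
#'
#' @param log an [event_log()].
#' @param reference_days length of the reference window in days (default 90,
#'   i.e. roughly the first three months).
#' @param slot_minutes appointment-grid step used for slot features.
#' @param n_servers server count used for `ExpectedDelayNextExam`'s clearance
#'   estimate; defaults to the number of distinct resources seen in the log.
#' @return A `facility_profile` list: `durations` (named numeric vector of
#'   median minutes per exam code), `fallback` (facility median),
#'   `facility_type`, `slot_minutes`, `n_servers`.
#' @export
facility_profile <- function(log, reference_days = 90, slot_minutes = 30,
                             n_servers = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (!nrow(log)) stopf("facility_profile: empty reference log")
  days <- ts_day(log$arrival_time)
  cutoff <- min(days) + reference_days
  ref <- log[days < cutoff, , drop = FALSE]
  if (!nrow(ref)) stopf("facility_profile: empty reference period")
  dur <- mins_between(ref$end_time, ref$begin_time)
  durations <- vapply(split(dur, ref$exam_code), stats::median, numeric(1))
  n_servers <- n_servers %||%
    max(1L, length(unique(log$resource_id[nzchar(log$resource_id)])))
  structure(list(
    durations = durations,
    fallback = stats::median(dur),
    facility_type = facility_type_of(log),
    slot_minutes = as.integer(slot_minutes),
    n_servers = as.integer(n_servers),
    reference_end = cutoff
  ), class = "facility_profile")
}

#' @export
print.facility_profile <- function(x, ...) {
  cat(sprintf(
    "<facility_profile> %s: %d exam codes (fallback median %.0f min), slot %d min, %d servers\n",
    x$facility_type, length(x$durations), x$fallback, x$slot_minutes,
    x$n_servers))
  invisible(x)
}

#' Expected service duration of an exam code
#'
#' @param exam_code character vector of exam codes.
#' @param profile a [facility_profile()].
#' @return Numeric minutes: the reference-period median for known codes, the
#'   facility fallback median otherwise.
#' @examples
#' \dontrun{expected_duration("EX-NEURO", profile)}
#' @export
expected_duration <- function(exam_code, profile) {
  stopifnot(inherits(profile, "facility_profile"))
  out <- unname(profile$durations[exam_code])
  out[is.na(out)] <- profile$fallback
  out
}
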