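#' Facility event logs
#'
#' An `event_log` is the canonical container for Hospital Information System
#' style visit records: one row per patient visit with its scheduled, arrival,
#' begin and end timestamps plus exam metadata.  Rows are kept sorted by
#' arrival time (ties by `visit_id`) and validated against the basic workflow
#' invariants (`arrival <= begin <= end`, unique visit ids).
#'
#' For walk-in facilities no real schedule exists, so at ingest the scheduled
#' time of every record is set equal to its arrival time.  This proxy makes
#' schedule-based features computable (if degenerate) on walk-in logs and makes
#' the delay of a walk-in visit coincide with its wait.
#'
#' @param visits data.frame with the columns listed in [log_columns()].
#'   Timestamp columns may be `POSIXct` or ISO 8601 strings
#'   (`"2018-03-01T09:30"`).
#' @param facility_id single string naming the facility.
#' @param facility_type one of `"scheduled"`, `"hybrid"`, `"walkin"`.
#'
#' @return An object of class `event_log`: a data.frame of visit records with
#'   attributes `facility_id` and `facility_type`.
#' @examples
#' visits <- data.frame(
#'   visit_id = "v1", facility_id = "F1", exam_code = "MR1",
#'   exam_category = "neuro", contrast_flag = "none",
#'   scheduled_time = "2018-03-01T09:00", arrival_time = "2018-03-01T08:50",
#'   begin_time = "2018-03-01T09:05", end_time = "2018-03-01T09:45",
#'   resource_id = "R01", patient_age = 54, is_outpatient = TRUE,
#'   addon_time = ""
#' )
#' log <- event_log(visits, facility_id = "F1", facility_type = "scheduled")
#' compute_target(log)  # delay = begin - scheduled = 5 minutes
#' @export
event_log <- function(visits, facility_id, facility_type) {
  facility_type <- match.arg(facility_type, FACILITY_TYPES)
  stopifnot(is.character(facility_id), length(facility_id) == 1L)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)

  missing_cols <- setdiff(LOG_COLUMNS, names(visits))
  if (length(missing_cols)) {
    stopf("event log is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  visits <- visits[LOG_COLUMNS]

  for (col in TS_COLUMNS) {
    if (!inherits(visits[[col]], "POSIXct")) {
      visits[[col]] <- parse_ts(as.character(visits[[col]]))
    } else {
      attr(visits[[col]], "tzone") <- "UTC"
    }
  }
  visits$visit_id <- as.character(visits$visit_id)
  visits$exam_code <- as.character(visits$exam_code)
  visits$exam_category <- as.character(visits$exam_category)
  visits$contrast_flag <- as.character(visits$contrast_flag)
  visits$resource_id <- as.character(visits$resource_id)
  visits$patient_age <- suppressWarnings(as.numeric(visits$patient_age))
  visits$is_outpatient <- as.logical(visits$is_outpatient)

  if (nrow(visits)) {
    if (anyDuplicated(visits$visit_id)) {
      stopf("duplicate visit_id in event log: %s",
            visits$visit_id[anyDuplicated(visits$visit_id)][1L])
    }
    bad_cat <- !is.na(visits$exam_category) & nzchar(visits$exam_category) &
      !visits$exam_category %in% EXAM_CATEGORIES
    if (any(bad_cat)) {
      stopf("unknown exam_category: %s", visits$exam_category[bad_cat][1L])
    }
    # Walk-in proxy: arrival stands in for the (non-existent) schedule.
    if (facility_type == "walkin") {
      visits$scheduled_time <- visits$arrival_time
    }
    core_na <- is.na(visits$arrival_time) | is.na(visits$begin_time) |
      is.na(visits$end_time)
    if (any(core_na)) {
      stopf("row %d: arrival/begin/end timestamps are required",
            which(core_na)[1L])
    }
    bad <- which(mins_between(visits$begin_time, visits$arrival_time) < 0)
    if (length(bad)) {
      stopf("row %d (visit %s): begin_time precedes arrival_time",
            bad[1L], visits$visit_id[bad[1L]])
    }
    bad <- which(mins_between(visits$end_time, visits$begin_time) < 0)
    if (length(bad)) {
      stopf("row %d (visit %s): end_time precedes begin_time",
            bad[1L], visits$visit_id[bad[1L]])
    }
    visits <- visits[order(visits$arrival_time, visits$visit_id), , drop = FALSE]
    rownames(visits) <- NULL
  }

  structure(visits,
            facility_id = facility_id,
            facility_type = facility_type,
            class = c("event_log", "data.frame"))
}

FACILITY_TYPES <- c("scheduled", "hybrid", "walkin")

EXAM_CATEGORIES <- c("MSK", "cardiac", "vascular", "abdominal", "neuro",
                     "pediatric", "thoracic", "other", "combined")

LOG_COLUMNS <- c("visit_id", "facility_id", "exam_code", "exam_category",
                 "contrast_flag", "scheduled_time", "arrival_time",
                 "begin_time", "end_time", "resource_id", "patient_age",
                 "is_outpatient", "addon_time")

TS_COLUMNS <- c("scheduled_time", "arrival_time", "begin_time", "end_time",
                "addon_time")

#' Event-log column schema
#'
#' @return Character vector of the fixed CSV column order used by
#'   [read_event_log()] and [write_event_log()].
#' @export
log_columns <- function() LOG_COLUMNS

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> facility %s (%s): %d visits",
              attr(x, "facility_id"), attr(x, "facility_type"), nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", %s to %s",
                format(min(ts_day(x$arrival_time))),
                format(max(ts_day(x$arrival_time)))))
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

facility_type_of <- function(log) attr(log, "facility_type")
facility_id_of <- function(log) attr(log, "facility_id")

#' Read a facility event log from CSV
#'
#' Expects the fixed header of [log_columns()]; empty strings encode absent
#' optional fields.  Timestamps must be ISO 8601 at minute precision
#' (`"2018-03-01T09:30"`).
#'
#' @param path path to a CSV file.
#' @param facility_type one of `"scheduled"`, `"hybrid"`, `"walkin"`.
#' @param facility_id optional facility id; defaults to the `facility_id`
#'   column of the file (or `"?"` for an empty file).
#' @return An [event_log()].
#' @export
read_event_log <- function(path, facility_type, facility_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(LOG_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw)) {
    raw$patient_age <- ifelse(nzchar(raw$patient_age), raw$patient_age, NA)
    raw$is_outpatient <- raw$is_outpatient %in% c("TRUE", "true", "1")
  }
  fid <- facility_id %||% (if (nrow(raw)) raw$facility_id[1L] else "?")
  event_log(raw, facility_id = fid, facility_type = facility_type)
}

#' Write a facility event log to CSV
#'
#' Columns are written in the fixed [log_columns()] order with ISO 8601
#' minute-precision timestamps; `NA` optional fields become empty strings.
#'
#' @param log an [event_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  out <- as.data.frame(log)
  for (col in TS_COLUMNS) out[[col]] <- format_ts(out[[col]])
  out$patient_age <- ifelse(is.na(out$patient_age), "", as.character(out$patient_age))
  out$is_outpatient <- ifelse(is.na(out$is_outpatient), "",
                              ifelse(out$is_outpatient, "TRUE", "FALSE"))
  for (col in c("exam_category", "contrast_flag", "resource_id")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write event log to %s", path)
  invisible(path)
}

#' Delay / wait target of each visit
#'
#' The prediction target of the whole pipeline.  For scheduled and hybrid
#' facilities the target is the *delay*: begin minus scheduled time, negative
#' when a patient is seen before their scheduled time.  For walk-in facilities
#' it is the *wait*: begin minus arrival, nonnegative by construction.  Under
#' the walk-in schedule proxy the two coincide on walk-in logs.
#'
#' @param log an [event_log()] (or a data.frame of visit rows).
#' @param facility_type facility type; defaults to the log's own type.
#' @return Numeric vector of minutes, one per visit.
#' @export
compute_target <- function(log, facility_type = NULL) {
  facility_type <- facility_type %||% facility_type_of(log)
  facility_type <- match.arg(facility_type, FACILITY_TYPES)
  if (!nrow(log)) return(numeric(0))
  if (is.null(log$begin_time) || anyNA(log$begin_time)) {
    stopf("compute_target: begin_time is required for every visit")
  }
  if (facility_type == "walkin") {
    mins_between(log$begin_time, log$arrival_time)
  } else {
    if (anyNA(log$scheduled_time)) {
      stopf("compute_target: missing scheduled_time at a %s facility",
            facility_type)
    }
    mins_between(log$begin_time, log$scheduled_time)
  }
}

#' Summarize an event log
#'
#' @param object an [event_log()].
#' @param n_servers optional server count for the utilization column; defaults
#'   to the number of distinct `resource_id` values.
#' @param ... unused.
#' @return A one-row data.frame: visit count, distinct days, visits/day, mean
#'   and max target (delay or wait, minutes), and mean server utilization over
#'   the span of each day's activity.
#' @export
summary.event_log <- function(object, n_servers = NULL, ...) {
  if (!nrow(object)) stopf("summarize: empty event log")
  days <- ts_day(object$arrival_time)
  n_days <- length(unique(days))
  target <- compute_target(object)
  n_servers <- n_servers %||% max(1L, length(unique(object$resource_id[nzchar(object$resource_id)])))
  busy <- sum(mins_between(object$end_time, object$begin_time))
  span <- sum(vapply(split(seq_len(nrow(object)), days), function(i) {
    max(mins_between(max(object$end_time[i]), min(object$begin_time[i])), 1)
  }, numeric(1)))
  data.frame(
    facility_id = facility_id_of(object),
    facility_type = facility_type_of(object),
    n_visits = nrow(object),
    n_days = n_days,
    visits_per_day = nrow(object) / n_days,
    mean_target = mean(target),
    max_target = max(target),
    utilization = busy / (n_servers * span)
  )
}
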