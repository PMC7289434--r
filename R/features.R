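#' Queue snapshot at a time point
#'
#' Reconstructs the operational state of a facility at an arbitrary instant
#' `t` from its event log, using half-open membership rules: a visit is *in
#' line* when `arrival <= t < begin`, *in progress* when `begin <= t < end`
#' (so a visit beginning exactly at `t` counts as in progress, not in line)
#' and *completed today* when `end <= t` on the same calendar day.  Membership
#' depends only on events timestamped at or before `t`.
#'
#' @param log an [event_log()].
#' @param t a `POSIXct` time (or ISO 8601 string).
#' @param exclude optional visit id(s) to leave out of every set — used at
#'   prediction time to exclude the index visit itself (which otherwise sits
#'   in line from the instant it arrives).
#' @return A `queue_snapshot` list of visit-id vectors: `in_line`,
#'   `in_progress`, `completed_today`, `begun_today` (ordered by begin time).
#' @examples
#' \dontrun{snap <- queue_snapshot(log, "2018-03-01T09:15")}
#' @export
queue_snapshot <- function(log, t, exclude = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (is.character(t)) t <- parse_ts(t)
  day <- ts_day(t)
  same_day <- ts_day(log$arrival_time) == day &
    !log$visit_id %in% exclude
  in_line <- same_day & log$arrival_time <= t & log$begin_time > t
  in_prog <- same_day & log$begin_time <= t & log$end_time > t
  completed <- same_day & log$end_time <= t
  begun <- same_day & log$begin_time <= t
  ord <- order(log$begin_time[begun], log$arrival_time[begun],
               log$visit_id[begun])
  structure(list(
    t = t,
    in_line = log$visit_id[in_line],
    in_progress = log$visit_id[in_prog],
    completed_today = log$visit_id[completed],
    begun_today = log$visit_id[begun][ord]
  ), class = "queue_snapshot")
}

#' @export
print.queue_snapshot <- function(x, ...) {
  cat(sprintf("<queue_snapshot> %s: %d in line, %d in progress, %d completed today\n",
              format_ts(x$t), length(x$in_line), length(x$in_progress),
              length(x$completed_today)))
  invisible(x)
}

# Internal: augment an event_log with per-visit day, target and frozen
# expected durations.
prepare_log <- function(log, profile) {
  df <- as.data.frame(log)
  df$day <- ts_day(df$arrival_time)
  df$target <- compute_target(log, profile$facility_type)
  df$exp_dur <- expected_duration(df$exam_code, profile)
  df
}

# Internal: numeric event times for one operating day, in minutes relative to
# that day's midnight (events on other days land outside [0, 1440) and so
# drop out of the day-scoped predicates naturally).
day_frame <- function(dd) {
  day0 <- as.POSIXct(paste0(format(dd$day[1L]), "T00:00"),
                     format = TS_FORMAT, tz = "UTC")
  dd$arr <- mins_between(dd$arrival_time, day0)
  dd$sch <- mins_between(dd$scheduled_time, day0)
  dd$beg <- mins_between(dd$begin_time, day0)
  dd$fin <- mins_between(dd$end_time, day0)
  dd$add <- mins_between(dd$addon_time, day0)
  dd
}

# Internal: the 84 feature values for row `i` of the single-day frame `d`
# (all rows share one calendar day; `d` includes the index row, which is
# excluded from every state and count set).  Windows are half-open (t-w, t];
# delay/wait history uses only visits with begin <= t.
day_features <- function(d, i, profile) {
  t <- d$arr[i]
  slot <- profile$slot_minutes
  o <- setdiff(seq_len(nrow(d)), i)  # everything except the index visit
  arr <- d$arr[o]; sch <- d$sch[o]; beg <- d$beg[o]; fin <- d$fin[o]
  tgt <- d$target[o]; edur <- d$exp_dur[o]

  line <- arr <= t & beg > t
  prog <- beg <= t & fin > t
  begun <- beg <= t

  line_at <- function(tt) if (tt < 0) 0L else sum(arr <= tt & beg > tt)
  win <- function(x, w) x > t - w & x <= t

  # delay/wait history, most recent first (ties: arrival, then original order)
  bo <- o[begun][order(beg[begun], arr[begun], o[begun], decreasing = TRUE)]
  recent <- d$target[bo]
  pad <- function(k) c(recent, numeric(k))[seq_len(k)]

  g_next <- (t %/% slot + 1) * slot
  next_slot <- sch >= g_next & sch < g_next + slot

  sum_ttc_prog <- sum(pmax(edur[prog] - (t - beg[prog]), 0))
  future_sch <- sch[sch > t]
  next_s <- if (length(future_sch)) min(future_sch) else NA_real_
  clearance <- t + sum_ttc_prog / profile$n_servers

  same_code <- d$exam_code[o] == d$exam_code[i]
  cat_count <- function(cc) sum(line & d$exam_category[o] %in% cc)
  con_line <- d$contrast_flag[o]

  lt <- as.POSIXlt(d$scheduled_time[i], tz = "UTC")

  c(
    LineCount0Strict = sum(line & sch > t),
    LineCount0 = sum(line),
    LineCount1 = line_at(t - 15),
    LineCount2 = line_at(t - 30),
    LineCount3 = line_at(t - 45),
    LineCount4 = line_at(t - 60),
    FlowCount30 = sum(win(beg, 30)),
    FlowCount60 = sum(win(beg, 60)),
    ScheduledFlowCount30 = sum(win(sch, 30)),
    ScheduledFlowCount60 = sum(win(sch, 60)),
    FutureFlowCount30 = sum(sch > t & sch <= t + 30),
    FutureFlowCount60 = sum(sch > t & sch <= t + 60),
    AheadCount = sum(sch < d$sch[i]),
    IsFirst = as.numeric(!any(sch < d$sch[i])),
    IsLast = as.numeric(!any(sch > d$sch[i])),
    NoneInLine = as.numeric(sum(line) == 0),
    SumWaits = sum(t - arr[line]),
    NumCustomersLast30 = sum(win(arr, 30)),
    NumCustomersLast60 = sum(win(arr, 60)),
    NumCustomersLast120 = sum(win(arr, 120)),
    NumScheduledNextSlot = sum(next_slot),
    NumScheduledNext60 = sum(sch > t & sch <= t + 60),
    AvgWaitForDay = if (any(begun)) mean(tgt[begun]) else 0,
    NumCompletedInLast30 = sum(win(fin, 30)),
    NumCompletedInLast60 = sum(win(fin, 60)),
    NumCompletedInLast120 = sum(win(fin, 120)),
    NumCompletedToday = sum(fin <= t),
    DelayedInLine = sum(line & t - sch > 0),
    MinTime = if (any(begun)) min(tgt[begun]) else 0,
    MaxTime = if (any(begun)) max(tgt[begun]) else 0,
    DelayCount = sum(begun & tgt > 0),
    DelayCountLastHour = sum(win(beg, 60) & tgt > 0),
    AvgWaitLast30 = if (any(win(beg, 30))) mean(tgt[win(beg, 30)]) else 0,
    AvgWaitLast60 = if (any(win(beg, 60))) mean(tgt[win(beg, 60)]) else 0,
    AvgWaitLast120 = if (any(win(beg, 120))) mean(tgt[win(beg, 120)]) else 0,
    SumTimeToCompleteNextSlot = sum(edur[next_slot]),
    SumTimeToCompleteNext60 = sum(edur[sch > t & sch <= t + 60]),
    InProgressSize = sum(prog),
    SumTimeToCompleteInProgress = sum_ttc_prog,
    NoneCompleted = as.numeric(sum(fin <= t) == 0),
    NoneInProgress = as.numeric(sum(prog) == 0),
    SumInProgress = sum(t - beg[prog]),
    MostRecent1 = pad(1)[1], MostRecent2 = pad(2)[2],
    MostRecent3 = pad(3)[3], MostRecent4 = pad(4)[4],
    MostRecent5 = pad(5)[5],
    AvgWaitLast2Customers = mean(pad(2)),
    AvgWaitLast4Customers = mean(pad(4)),
    AvgWaitLast8Customers = mean(pad(8)),
    Median5 = stats::median(pad(5)),
    NumAddOnsToday = sum(!is.na(d$add[o]) & d$add[o] <= t),
    NumAddOnsLast60 = sum(!is.na(d$add[o]) & d$add[o] > t - 60 & d$add[o] <= t),
    SumHowEarlyWaiting = sum(sch[line] - arr[line]),
    AvgHowEarlyWaiting = if (any(line)) mean(sch[line] - arr[line]) else 0,
    SumDelayWaitingInLine = sum(t - sch[line]),
    SumDelayInProgress = sum(beg[prog] - sch[prog]),
    AvgAgePeopleWaiting = {
      ages <- d$patient_age[o][line]
      if (length(ages) && any(!is.na(ages))) mean(ages, na.rm = TRUE) else 0
    },
    OutpatientWaitingCount = sum(d$is_outpatient[o][line], na.rm = TRUE),
    NumScannersInUseToday = length(unique(d$resource_id[o][begun & nzchar(d$resource_id[o])])),
    WithContrastCountWaiting = sum(line & con_line == "with"),
    WithandWithoutContrastCountWaiting = sum(line & con_line == "with_and_without"),
    WithContrastCountInProgress = sum(prog & con_line == "with"),
    WithandWithoutContrastCountInProgress = sum(prog & con_line == "with_and_without"),
    ExpectedDelayNextExam = if (is.na(next_s)) 0 else max(0, clearance - next_s),
    SumDelayWaitingByExamCode = sum(t - sch[line & same_code]),
    AvgWaitByTaskTypeLine = if (any(line & same_code)) mean(t - arr[line & same_code]) else 0,
    SumWaitByTaskTypeLine = sum(t - arr[line & same_code]),
    MSKCount = cat_count("MSK"),
    CardiacCount = cat_count("cardiac"),
    VascularCount = cat_count("vascular"),
    AbdominalCount = cat_count("abdominal"),
    NeuroCount = cat_count("neuro"),
    PediatricCount = cat_count("pediatric"),
    ThoracicCount = cat_count("thoracic"),
    DayOfYear = lt$yday + 1,
    Month = lt$mon + 1,
    DayOfWeek = ((lt$wday + 6) %% 7) + 1,
    StartTime = t / 60,
    StartTime2 = (t / 60)^2,
    StartTime3 = (t / 60)^3,
    StartTime4 = (t / 60)^4,
    BeforeSlot = t - (t %/% slot) * slot,
    AfterSlot = (t %/% slot + 1) * slot - t
  )
}

#' Compute the 84-feature vector for one index visit
#'
#' All features are evaluated *as of* the index visit's arrival time (the
#' prediction time): the index visit itself is excluded from every state and
#' count set; trailing windows are half-open `(t-w, t]`; schedule-derived
#' features may use schedule entries with any timestamp (the schedule is known
#' in advance); delay/wait-history features use only visits whose exam has
#' begun by `t` (a visit's delay becomes known at its begin time).  Feature
#' state is scoped to the index visit's operating day.
#'
#' @param log an [event_log()].
#' @param index_visit a visit id present in `log` (or a one-row subset of the
#'   log).
#' @param catalog a [feature_catalog()].
#' @param profile a [facility_profile()].
#' @return Named numeric vector of 84 feature values in catalog order.
#' @export
compute_features <- function(log, index_visit, catalog = feature_catalog(),
                             profile) {
  stopifnot(inherits(log, "event_log"), inherits(profile, "facility_profile"))
  id <- if (is.character(index_visit)) index_visit else index_visit$visit_id
  i <- match(id, log$visit_id)
  if (is.na(i)) stopf("compute_features: visit %s not found in log", id)
  df <- prepare_log(log, profile)
  d <- day_frame(df[df$day == df$day[i], , drop = FALSE])
  vals <- day_features(d, match(id, d$visit_id), profile)
  vals[catalog$name]
}

#' Build the per-visit feature matrix for a whole log
#'
#' One row per visit, with the 84 catalog features evaluated at that visit's
#' arrival time plus the facility-appropriate delay/wait target.
#'
#' @inheritParams compute_features
#' @return A `feature_matrix`: data.frame with columns `visit_id`,
#'   `prediction_time`, the 84 features in catalog order, and `target`
#'   (minutes).  Attributes carry the facility id/type and the catalog.
#' @examples
#' \dontrun{fm <- featurize_log(sim$log, feature_catalog(), profile)}
#' @export
featurize_log <- function(log, catalog = feature_catalog(), profile) {
  stopifnot(inherits(log, "event_log"), inherits(profile, "facility_profile"))
  df <- prepare_log(log, profile)
  rows <- vector("list", length(unique(df$day)))
  k <- 0L
  for (day_df in split(df, df$day)) {
    day_df <- day_frame(day_df)
    m <- matrix(0, nrow(day_df), 84L)
    v <- NULL
    for (i in seq_len(nrow(day_df))) {
      v <- day_features(day_df, i, profile)
      m[i, ] <- v
    }
    colnames(m) <- names(v)
    out <- data.frame(visit_id = day_df$visit_id, stringsAsFactors = FALSE)
    out$prediction_time <- day_df$arrival_time
    out <- cbind(out, as.data.frame(m))
    out$target <- day_df$target
    k <- k + 1L
    rows[[k]] <- out
  }
  fm <- do.call(rbind, rows[seq_len(k)])
  fm <- fm[c("visit_id", "prediction_time", catalog$name, "target")]
  rownames(fm) <- NULL
  structure(fm,
            facility_id = facility_id_of(log),
            facility_type = facility_type_of(log),
            catalog = catalog,
            class = c("feature_matrix", "data.frame"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s (%s): %d visits x %d features (+ target)\n",
              attr(x, "facility_id"), attr(x, "facility_type"), nrow(x),
              ncol(x) - 3L))
  invisible(x)
}

#' Names of the feature columns of a feature matrix
#' @param matrix a `feature_matrix` (or plain data.frame from one).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(matrix) {
  setdiff(names(matrix), c("visit_id", "prediction_time", "target"))
}

#' Write a feature matrix to CSV
#' @param matrix a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  out <- as.data.frame(matrix)
  out$prediction_time <- format_ts(out$prediction_time)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return A `feature_matrix` data.frame.
#' @export
read_feature_matrix <- function(path) {
  fm <- utils::read.csv(path, check.names = FALSE)
  fm$prediction_time <- parse_ts(fm$prediction_time)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
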