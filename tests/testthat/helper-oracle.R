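# Independent brute-force oracle for the 84-feature engine: recomputes every
# feature for one index visit by naive filtering of the raw log, sharing no
# code with the engine's per-day vectorized path.

oracle_features <- function(log, id, profile) {
  df <- as.data.frame(log)
  df$day <- as.Date(df$arrival_time, tz = "UTC")
  i <- which(df$visit_id == id)
  stopifnot(length(i) == 1L)
  t <- df$arrival_time[i]
  mins <- function(a, b) as.numeric(difftime(a, b, units = "mins"))
  mod <- function(x) {
    lt <- as.POSIXlt(x, tz = "UTC")
    lt$hour * 60 + lt$min
  }
  tgt_of <- function(rows) {
    if (attr(log, "facility_type") == "walkin") {
      mins(rows$begin_time, rows$arrival_time)
    } else {
      mins(rows$begin_time, rows$scheduled_time)
    }
  }
  ed_of <- function(code) {
    v <- unname(profile$durations[code])
    v[is.na(v)] <- profile$fallback
    v
  }

  o <- df[df$day == df$day[i] & df$visit_id != id, , drop = FALSE]
  line <- o[o$arrival_time <= t & o$begin_time > t, , drop = FALSE]
  prog <- o[o$begin_time <= t & o$end_time > t, , drop = FALSE]
  begun <- o[o$begin_time <= t, , drop = FALSE]
  done <- o[o$end_time <= t, , drop = FALSE]

  line_at <- function(minutes_back) {
    tt <- t - minutes_back * 60
    if (as.Date(tt, tz = "UTC") != df$day[i]) return(0)
    nrow(o[o$arrival_time <= tt & o$begin_time > tt, ])
  }
  in_win <- function(x, w) x > t - w * 60 & x <= t

  # delay/wait history: most recent = latest begin (ties: arrival, visit_id)
  begun <- begun[order(begun$begin_time, begun$arrival_time, begun$visit_id), ,
                 drop = FALSE]
  hist_tgt <- rev(tgt_of(begun))
  padk <- function(k) c(hist_tgt, numeric(k))[seq_len(k)]

  slot <- profile$slot_minutes
  tmod <- mod(t)
  g_next <- (tmod %/% slot + 1) * slot
  sch_mod <- mod(o$scheduled_time)
  nxt_slot <- o[sch_mod >= g_next & sch_mod < g_next + slot, , drop = FALSE]
  nxt60 <- o[o$scheduled_time > t & mins(o$scheduled_time, t) <= 60, , drop = FALSE]

  sum_ttc_prog <- if (nrow(prog)) {
    sum(pmax(ed_of(prog$exam_code) - mins(t, prog$begin_time), 0))
  } else 0
  fut <- o$scheduled_time[o$scheduled_time > t]
  exp_delay_next <- if (!length(fut)) 0 else {
    max(0, sum_ttc_prog / profile$n_servers - mins(min(fut), t))
  }

  line_code <- line[line$exam_code == df$exam_code[i], , drop = FALSE]
  ncat <- function(cc) sum(line$exam_category == cc, na.rm = TRUE)
  lt_s <- as.POSIXlt(df$scheduled_time[i], tz = "UTC")
  mean0 <- function(x) if (length(x)) mean(x) else 0

  out <- c(
    LineCount0Strict = sum(line$scheduled_time > t),
    LineCount0 = nrow(line),
    LineCount1 = line_at(15), LineCount2 = line_at(30),
    LineCount3 = line_at(45), LineCount4 = line_at(60),
    FlowCount30 = sum(in_win(o$begin_time, 30)),
    FlowCount60 = sum(in_win(o$begin_time, 60)),
    ScheduledFlowCount30 = sum(in_win(o$scheduled_time, 30)),
    ScheduledFlowCount60 = sum(in_win(o$scheduled_time, 60)),
    FutureFlowCount30 = sum(o$scheduled_time > t & mins(o$scheduled_time, t) <= 30),
    FutureFlowCount60 = sum(o$scheduled_time > t & mins(o$scheduled_time, t) <= 60),
    AheadCount = sum(o$scheduled_time < df$scheduled_time[i]),
    IsFirst = as.numeric(sum(o$scheduled_time < df$scheduled_time[i]) == 0),
    IsLast = as.numeric(sum(o$scheduled_time > df$scheduled_time[i]) == 0),
    NoneInLine = as.numeric(nrow(line) == 0),
    SumWaits = sum(mins(t, line$arrival_time)),
    NumCustomersLast30 = sum(in_win(o$arrival_time, 30)),
    NumCustomersLast60 = sum(in_win(o$arrival_time, 60)),
    NumCustomersLast120 = sum(in_win(o$arrival_time, 120)),
    NumScheduledNextSlot = nrow(nxt_slot),
    NumScheduledNext60 = nrow(nxt60),
    AvgWaitForDay = mean0(tgt_of(begun)),
    NumCompletedInLast30 = sum(in_win(o$end_time, 30)),
    NumCompletedInLast60 = sum(in_win(o$end_time, 60)),
    NumCompletedInLast120 = sum(in_win(o$end_time, 120)),
    NumCompletedToday = nrow(done),
    DelayedInLine = sum(mins(t, line$scheduled_time) > 0),
    MinTime = if (nrow(begun)) min(tgt_of(begun)) else 0,
    MaxTime = if (nrow(begun)) max(tgt_of(begun)) else 0,
    DelayCount = sum(tgt_of(begun) > 0),
    DelayCountLastHour = sum(in_win(begun$begin_time, 60) & tgt_of(begun) > 0),
    AvgWaitLast30 = mean0(tgt_of(begun[in_win(begun$begin_time, 30), ])),
    AvgWaitLast60 = mean0(tgt_of(begun[in_win(begun$begin_time, 60), ])),
    AvgWaitLast120 = mean0(tgt_of(begun[in_win(begun$begin_time, 120), ])),
    SumTimeToCompleteNextSlot = sum(ed_of(nxt_slot$exam_code)),
    SumTimeToCompleteNext60 = sum(ed_of(nxt60$exam_code)),
    InProgressSize = nrow(prog),
    SumTimeToCompleteInProgress = sum_ttc_prog,
    NoneCompleted = as.numeric(nrow(done) == 0),
    NoneInProgress = as.numeric(nrow(prog) == 0),
    SumInProgress = sum(mins(t, prog$begin_time)),
    MostRecent1 = padk(1)[1], MostRecent2 = padk(2)[2],
    MostRecent3 = padk(3)[3], MostRecent4 = padk(4)[4],
    MostRecent5 = padk(5)[5],
    AvgWaitLast2Customers = mean(padk(2)),
    AvgWaitLast4Customers = mean(padk(4)),
    AvgWaitLast8Customers = mean(padk(8)),
    Median5 = median(padk(5)),
    NumAddOnsToday = sum(!is.na(o$addon_time) & o$addon_time <= t),
    NumAddOnsLast60 = sum(!is.na(o$addon_time) & in_win(o$addon_time, 60)),
    SumHowEarlyWaiting = sum(mins(line$scheduled_time, line$arrival_time)),
    AvgHowEarlyWaiting = mean0(mins(line$scheduled_time, line$arrival_time)),
    SumDelayWaitingInLine = sum(mins(t, line$scheduled_time)),
    SumDelayInProgress = sum(mins(prog$begin_time, prog$scheduled_time)),
    AvgAgePeopleWaiting = if (nrow(line) && any(!is.na(line$patient_age))) {
      mean(line$patient_age, na.rm = TRUE)
    } else 0,
    OutpatientWaitingCount = sum(line$is_outpatient, na.rm = TRUE),
    NumScannersInUseToday = length(unique(begun$resource_id[nzchar(begun$resource_id)])),
    WithContrastCountWaiting = sum(line$contrast_flag == "with"),
    WithandWithoutContrastCountWaiting = sum(line$contrast_flag == "with_and_without"),
    WithContrastCountInProgress = sum(prog$contrast_flag == "with"),
    WithandWithoutContrastCountInProgress = sum(prog$contrast_flag == "with_and_without"),
    ExpectedDelayNextExam = exp_delay_next,
    SumDelayWaitingByExamCode = sum(mins(t, line_code$scheduled_time)),
    AvgWaitByTaskTypeLine = mean0(mins(t, line_code$arrival_time)),
    SumWaitByTaskTypeLine = sum(mins(t, line_code$arrival_time)),
    MSKCount = ncat("MSK"), CardiacCount = ncat("cardiac"),
    VascularCount = ncat("vascular"), AbdominalCount = ncat("abdominal"),
    NeuroCount = ncat("neuro"), PediatricCount = ncat("pediatric"),
    ThoracicCount = ncat("thoracic"),
    DayOfYear = lt_s$yday + 1,
    Month = lt_s$mon + 1,
    DayOfWeek = ((lt_s$wday + 6) %% 7) + 1,
    StartTime = tmod / 60,
    StartTime2 = (tmod / 60)^2,
    StartTime3 = (tmod / 60)^3,
    StartTime4 = (tmod / 60)^4,
    BeforeSlot = tmod - (tmod %/% slot) * slot,
    AfterSlot = (tmod %/% slot + 1) * slot - tmod
  )
  out
}
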