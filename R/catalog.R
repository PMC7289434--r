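#' The 84-feature operational catalog
#'
#' Expands the full operational feature catalog: 84 named features in five
#' groups — congestion (57), customer (2), resource (1), task (15) and
#' time (9).  Every feature is computable from a plain visit event log at the
#' moment a patient arrives, with no patient-level covariates for the index
#' patient itself.
#'
#' Two applicability columns describe behaviour on walk-in logs, where arrival
#' time stands in for the non-existent schedule:
#' \describe{
#'   \item{`walkin_applicable`}{`FALSE` only for features *defined through the
#'     delay sign* (`DelayedInLine`, `DelayCount`, `DelayCountLastHour`): a
#'     walk-in wait is always positive, so "delayed" degenerates to a plain
#'     count and the feature loses its meaning.}
#'   \item{`requires_schedule`}{`TRUE` for features whose definition needs a
#'     real appointment grid or future bookings; under the arrival-as-schedule
#'     proxy these are computable but degenerate (e.g. `LineCount0Strict` is
#'     identically 0).  Used by the strict mode of [applicable_subset()].}
#' }
#'
#' @param facility_type optional; when `"walkin"`, the returned catalog keeps
#'   all 84 rows but the applicability columns describe that workflow.
#' @return A `feature_catalog`: data.frame with columns `name`, `group`,
#'   `window_minutes`, `walkin_applicable`, `requires_schedule`,
#'   `description`; exactly 84 rows in canonical (catalog) order.
#' @examples
#' cat84 <- feature_catalog()
#' nrow(cat84)            # 84
#' table(cat84$group)
#' @export
feature_catalog <- function(facility_type = NULL) {
  defs <- catalog_defs()
  stopifnot(nrow(defs) == 84L, !anyDuplicated(defs$name))
  structure(defs, facility_type = facility_type,
            class = c("feature_catalog", "data.frame"))
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d features in %d groups\n",
              nrow(x), length(unique(x$group))))
  print(table(factor(x$group, levels = unique(x$group))))
  invisible(x)
}

FEATURE_GROUPS <- c("congestion", "customer", "resource", "task", "time")

catalog_defs <- function() {
  row <- function(name, group, window = NA_integer_, walkin = TRUE,
                  sched = FALSE, desc = "") {
    data.frame(name = name, group = group, window_minutes = window,
               walkin_applicable = walkin, requires_schedule = sched,
               description = desc, stringsAsFactors = FALSE)
  }
  defs <- rbind(
    row("LineCount0Strict", "congestion", sched = TRUE,
        desc = "Patients in line whose scheduled time is after the current time"),
    row("LineCount0", "congestion", 0L, desc = "Patients in line at arrival"),
    row("LineCount1", "congestion", 15L, desc = "Patients in line 15 min before arrival"),
    row("LineCount2", "congestion", 30L, desc = "Patients in line 30 min before arrival"),
    row("LineCount3", "congestion", 45L, desc = "Patients in line 45 min before arrival"),
    row("LineCount4", "congestion", 60L, desc = "Patients in line 60 min before arrival"),
    row("FlowCount30", "congestion", 30L, desc = "Exams begun in the last 30 min"),
    row("FlowCount60", "congestion", 60L, desc = "Exams begun in the last 60 min"),
    row("ScheduledFlowCount30", "congestion", 30L, sched = TRUE,
        desc = "Patients scheduled in the 30 min before arrival"),
    row("ScheduledFlowCount60", "congestion", 60L, sched = TRUE,
        desc = "Patients scheduled in the 60 min before arrival"),
    row("FutureFlowCount30", "congestion", 30L, sched = TRUE,
        desc = "Patients scheduled in the 30 min after arrival"),
    row("FutureFlowCount60", "congestion", 60L, sched = TRUE,
        desc = "Patients scheduled in the 60 min after arrival"),
    row("AheadCount", "congestion",
        desc = "Patients scheduled before the current patient for the day"),
    row("IsFirst", "congestion", sched = TRUE,
        desc = "First scheduled patient of the day"),
    row("IsLast", "congestion", sched = TRUE,
        desc = "Last scheduled patient of the day"),
    row("NoneInLine", "congestion", desc = "No patients in line"),
    row("SumWaits", "congestion", desc = "Sum of waits so far of patients in line"),
    row("NumCustomersLast30", "congestion", 30L, desc = "Arrivals in the last 30 min"),
    row("NumCustomersLast60", "congestion", 60L, desc = "Arrivals in the last 60 min"),
    row("NumCustomersLast120", "congestion", 120L, desc = "Arrivals in the last 120 min"),
    row("NumScheduledNextSlot", "congestion", sched = TRUE,
        desc = "Patients scheduled in the next slot"),
    row("NumScheduledNext60", "congestion", 60L, sched = TRUE,
        desc = "Patients scheduled in the next 60 min"),
    row("AvgWaitForDay", "congestion", desc = "Mean delay/wait of today's begun exams"),
    row("NumCompletedInLast30", "congestion", 30L, desc = "Exams completed in the last 30 min"),
    row("NumCompletedInLast60", "congestion", 60L, desc = "Exams completed in the last 60 min"),
    row("NumCompletedInLast120", "congestion", 120L, desc = "Exams completed in the last 120 min"),
    row("NumCompletedToday", "congestion", desc = "Exams completed so far today"),
    row("DelayedInLine", "congestion", walkin = FALSE, sched = TRUE,
        desc = "Patients in line already past their scheduled time"),
    row("MinTime", "congestion", desc = "Minimum delay/wait so far today"),
    row("MaxTime", "congestion", desc = "Maximum delay/wait so far today"),
    row("DelayCount", "congestion", walkin = FALSE, sched = TRUE,
        desc = "Delayed exams (delay > 0) begun so far today"),
    row("DelayCountLastHour", "congestion", 60L, walkin = FALSE, sched = TRUE,
        desc = "Delayed exams begun in the last hour"),
    row("AvgWaitLast30", "congestion", 30L, desc = "Mean delay/wait of exams begun in last 30 min"),
    row("AvgWaitLast60", "congestion", 60L, desc = "Mean delay/wait of exams begun in last 60 min"),
    row("AvgWaitLast120", "congestion", 120L, desc = "Mean delay/wait of exams begun in last 120 min"),
    row("SumTimeToCompleteNextSlot", "congestion", sched = TRUE,
        desc = "Expected service minutes of exams scheduled in the next slot"),
    row("SumTimeToCompleteNext60", "congestion", 60L, sched = TRUE,
        desc = "Expected service minutes of exams scheduled in the next 60 min"),
    row("InProgressSize", "congestion", desc = "Exams in progress"),
    row("SumTimeToCompleteInProgress", "congestion",
        desc = "Expected remaining minutes of exams in progress"),
    row("NoneCompleted", "congestion", desc = "No exams completed today"),
    row("NoneInProgress", "congestion", desc = "No exams in progress"),
    row("SumInProgress", "congestion", desc = "Total elapsed minutes of exams in progress"),
    row("MostRecent1", "congestion", desc = "Delay/wait of the most recent patient"),
    row("MostRecent2", "congestion", desc = "Delay/wait of the 2nd most recent patient"),
    row("MostRecent3", "congestion", desc = "Delay/wait of the 3rd most recent patient"),
    row("MostRecent4", "congestion", desc = "Delay/wait of the 4th most recent patient"),
    row("MostRecent5", "congestion", desc = "Delay/wait of the 5th most recent patient"),
    row("AvgWaitLast2Customers", "congestion", desc = "Mean delay/wait of last 2 customers"),
    row("AvgWaitLast4Customers", "congestion", desc = "Mean delay/wait of last 4 customers"),
    row("AvgWaitLast8Customers", "congestion", desc = "Mean delay/wait of last 8 customers"),
    row("Median5", "congestion", desc = "Median delay/wait of last 5 customers"),
    row("NumAddOnsToday", "congestion", sched = TRUE,
        desc = "Patients added to today's schedule so far"),
    row("NumAddOnsLast60", "congestion", 60L, sched = TRUE,
        desc = "Patients added to the schedule in the last 60 min"),
    row("SumHowEarlyWaiting", "congestion", sched = TRUE,
        desc = "Sum of (scheduled - arrival) over patients in line"),
    row("AvgHowEarlyWaiting", "congestion", sched = TRUE,
        desc = "Mean of (scheduled - arrival) over patients in line"),
    row("SumDelayWaitingInLine", "congestion",
        desc = "Sum of delays-so-far of patients in line"),
    row("SumDelayInProgress", "congestion",
        desc = "Sum of delays/waits of exams in progress"),
    row("AvgAgePeopleWaiting", "customer", desc = "Mean age of patients in line"),
    row("OutpatientWaitingCount", "customer", desc = "Outpatients in line"),
    row("NumScannersInUseToday", "resource", desc = "Distinct scanners used so far today"),
    row("WithContrastCountWaiting", "task", desc = "Patients in line for a contrast exam"),
    row("WithandWithoutContrastCountWaiting", "task",
        desc = "Patients in line for a with-and-without-contrast exam"),
    row("WithContrastCountInProgress", "task", desc = "Contrast exams in progress"),
    row("WithandWithoutContrastCountInProgress", "task",
        desc = "With-and-without-contrast exams in progress"),
    row("ExpectedDelayNextExam", "task", sched = TRUE,
        desc = "Expected delay of the next scheduled exam"),
    row("SumDelayWaitingByExamCode", "task",
        desc = "Sum of delays-so-far of in-line patients with the index exam code"),
    row("AvgWaitByTaskTypeLine", "task",
        desc = "Mean wait-so-far of in-line patients with the index exam code"),
    row("SumWaitByTaskTypeLine", "task",
        desc = "Sum of waits-so-far of in-line patients with the index exam code"),
    row("MSKCount", "task", desc = "Patients in line for a musculoskeletal exam"),
    row("CardiacCount", "task", desc = "Patients in line for a cardiac exam"),
    row("VascularCount", "task", desc = "Patients in line for a vascular exam"),
    row("AbdominalCount", "task", desc = "Patients in line for an abdominal exam"),
    row("NeuroCount", "task", desc = "Patients in line for a neuro exam"),
    row("PediatricCount", "task", desc = "Patients in line for a pediatric exam"),
    row("ThoracicCount", "task", desc = "Patients in line for a thoracic exam"),
    row("DayOfYear", "time", desc = "Day of the year of the visit"),
    row("Month", "time", desc = "Month of the visit"),
    row("DayOfWeek", "time", desc = "ISO day of the week of the visit"),
    row("StartTime", "time", desc = "Fractional hour of arrival"),
    row("StartTime2", "time", desc = "Squared hour of arrival"),
    row("StartTime3", "time", desc = "Cubed hour of arrival"),
    row("StartTime4", "time", desc = "Fourth power of hour of arrival"),
    row("BeforeSlot", "time", sched = TRUE, desc = "Minutes since the previous slot grid point"),
    row("AfterSlot", "time", sched = TRUE, desc = "Minutes until the next slot grid point")
  )
  rownames(defs) <- NULL
  defs
}

#' Export the catalog as a data dictionary CSV
#'
#' @param catalog a [feature_catalog()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}
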