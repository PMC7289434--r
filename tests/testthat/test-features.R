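test_that("queue snapshots follow the half-open membership rules", {
  log <- toy_log()
  snap <- queue_snapshot(log, "2018-03-01T08:00")
  expect_length(snap$in_line, 0L)
  expect_length(snap$in_progress, 0L)
  expect_length(snap$completed_today, 0L)

  snap <- queue_snapshot(log, "2018-03-01T09:15", exclude = "C")
  expect_setequal(snap$in_line, c("A", "B"))
  expect_length(snap$in_progress, 0L)

  # a visit arriving exactly at t is in line unless excluded as the index
  expect_setequal(queue_snapshot(log, "2018-03-01T09:15")$in_line,
                  c("A", "B", "C"))

  # begin == t counts as in progress, not in line
  snap <- queue_snapshot(log, "2018-03-01T09:20", exclude = "C")
  expect_setequal(snap$in_line, "B")
  expect_setequal(snap$in_progress, "A")
  expect_length(intersect(snap$in_line, snap$in_progress), 0L)

  snap <- queue_snapshot(log, "2018-03-01T09:55")
  expect_setequal(snap$completed_today, c("A", "B"))
  expect_setequal(snap$in_progress, "C")
})

test_that("hand-computed toy features are reproduced", {
  log <- toy_log()
  prof <- toy_profile(log)
  v <- compute_features(log, "C", feature_catalog(), prof)
  expect_length(v, 84L)
  expect_equal(unname(v["LineCount0"]), 2)
  expect_equal(unname(v["SumWaits"]), 25)  # 15 + 10
  expect_equal(unname(v["InProgressSize"]), 0)
  expect_equal(unname(v["NumCustomersLast30"]), 2)
  expect_equal(unname(v["NoneInLine"]), 0)
  expect_equal(unname(v["StartTime"]), 9.25)
  expect_equal(unname(v["BeforeSlot"]), 15)
  expect_equal(unname(v["AfterSlot"]), 15)
})

test_that("the first visit of an empty day gets the empty-state defaults", {
  log <- toy_log()
  prof <- toy_profile(log)
  v <- compute_features(log, "A", feature_catalog(), prof)
  expect_equal(unname(v["LineCount0"]), 0)
  expect_equal(unname(v["NoneInLine"]), 1)
  expect_equal(unname(v["NoneInProgress"]), 1)
  expect_equal(unname(v["NoneCompleted"]), 1)
  expect_equal(unname(v["IsFirst"]), 1)
  expect_equal(unname(v[paste0("MostRecent", 1:5)]), rep(0, 5))
  expect_error(compute_features(log, "nope", feature_catalog(), prof),
               "not found")
})

test_that("expected durations are reference-period medians with fallback", {
  rows <- rbind(
    visit_row("a", "2018-01-01T09:00", "2018-01-01T09:00", "2018-01-01T09:10", code = "K1"),
    visit_row("b", "2018-01-01T10:00", "2018-01-01T10:00", "2018-01-01T10:20", code = "K1"),
    visit_row("c", "2018-01-01T11:00", "2018-01-01T11:00", "2018-01-01T11:40", code = "K1"),
    visit_row("d", "2018-01-01T12:00", "2018-01-01T12:00", "2018-01-01T12:35", code = "K2")
  )
  log <- event_log(rows, "T", "walkin")
  prof <- facility_profile(log, reference_days = 30, slot_minutes = 30)
  expect_equal(expected_duration("K1", prof), 20)   # median of 10, 20, 40
  expect_equal(expected_duration("K2", prof), 35)   # single observation
  expect_equal(expected_duration("K9", prof), prof$fallback)  # unseen code
  expect_equal(prof$fallback, median(c(10, 20, 40, 35)))
  expect_error(facility_profile(event_log(rows[0, ], "T", "walkin")), "empty")
})

test_that("featurize_log yields one row per visit with targets attached", {
  log <- toy_log()
  fm <- featurize_log(log, feature_catalog(), toy_profile(log))
  expect_equal(nrow(fm), 3L)
  expect_length(feature_names(fm), 84L)
  expect_equal(fm$target, c(20, 25, 25))
  expect_true(all(is.finite(as.matrix(fm[feature_names(fm)]))))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(feature_names(back), feature_names(fm))
  expect_equal(back$target, fm$target)
})

test_that("every feature matches the brute-force oracle on random logs", {
  n_checked <- 0L
  for (seed in 1:30) {
    type <- c("walkin", "scheduled", "hybrid")[seed %% 3 + 1]
    log <- random_small_log(seed, type)
    if (nrow(log) < 2) next
    prof <- facility_profile(log, reference_days = 2,
                             slot_minutes = 30, n_servers = 2)
    fm <- featurize_log(log, feature_catalog(), prof)
    for (id in log$visit_id) {
      expected <- oracle_features(log, id, prof)
      got <- unlist(fm[fm$visit_id == id, names(expected)])
      expect_equal(got, expected, tolerance = 1e-10,
                   info = paste("visit", id, "seed", seed, type))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("internal consistency identities hold on simulated data", {
  log <- random_small_log(101, "scheduled")
  prof <- facility_profile(log, reference_days = 2, slot_minutes = 30,
                           n_servers = 2)
  fm <- featurize_log(log, feature_catalog(), prof)
  expect_equal(fm$NoneInLine == 1, fm$LineCount0 == 0)
  expect_equal(fm$AvgHowEarlyWaiting * fm$LineCount0, fm$SumHowEarlyWaiting,
               tolerance = 1e-9)
  region <- fm$MSKCount + fm$CardiacCount + fm$VascularCount +
    fm$AbdominalCount + fm$NeuroCount + fm$PediatricCount + fm$ThoracicCount
  expect_true(all(region <= fm$LineCount0))
})

test_that("walk-in proxy degeneracies hold", {
  log <- random_small_log(55, "walkin")
  prof <- facility_profile(log, reference_days = 2, slot_minutes = 30)
  fm <- featurize_log(log, feature_catalog(), prof)
  expect_true(all(fm$LineCount0Strict == 0))
  expect_equal(fm$SumDelayWaitingInLine, fm$SumWaits)
  expect_true(all(fm$target >= 0))
})

test_that("features never leak information from after the prediction time", {
  for (seed in c(7, 8)) {
    log <- random_small_log(seed, c("scheduled", "walkin")[seed %% 2 + 1])
    if (nrow(log) < 3) next
    prof <- facility_profile(log, reference_days = 2, slot_minutes = 30,
                             n_servers = 2)
    fm <- featurize_log(log, feature_catalog(), prof)
    for (i in seq_len(nrow(log))) {
      t <- log$arrival_time[i]
      # censor every event after t: begins/ends move far into the future and
      # (at scheduled facilities) not-yet-arrived patients get an arbitrary
      # late same-day arrival; schedule entries are kept — they are known in
      # advance.  The feature row must not change.
      far <- t + 10000 * 60
      trunc_df <- as.data.frame(log)
      trunc_df$end_time[trunc_df$end_time > t] <- far + 60
      trunc_df$begin_time[trunc_df$begin_time > t] <- far
      if (flowsel:::facility_type_of(log) != "walkin") {
        day_end <- as.POSIXct(paste0(format(as.Date(t, tz = "UTC")), "T23:50"),
                              format = "%Y-%m-%dT%H:%M", tz = "UTC")
        trunc_df$arrival_time[trunc_df$arrival_time > t] <- day_end
      }
      trunc_log <- event_log(trunc_df, flowsel:::facility_id_of(log),
                             flowsel:::facility_type_of(log))
      got <- compute_features(trunc_log, log$visit_id[i],
                              feature_catalog(), prof)
      expect_equal(got, unlist(fm[fm$visit_id == log$visit_id[i],
                                  names(got)]),
                   tolerance = 1e-10, info = paste("row", i, "seed", seed))
    }
  }
})
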