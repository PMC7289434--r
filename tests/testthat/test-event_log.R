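test_that("logs validate ordering and workflow invariants", {
  log <- toy_log()
  expect_s3_class(log, "event_log")
  expect_equal(log$visit_id, c("A", "B", "C"))  # sorted by arrival

  bad <- visit_row("X", "2018-03-01T09:00", "2018-03-01T08:00", "2018-03-01T08:30")
  expect_error(event_log(bad, "T", "walkin"), "begin_time precedes arrival_time")

  dup <- rbind(visit_row("A", "2018-03-01T09:00", "2018-03-01T09:10", "2018-03-01T09:20"),
               visit_row("A", "2018-03-01T09:05", "2018-03-01T09:30", "2018-03-01T09:40"))
  expect_error(event_log(dup, "T", "walkin"), "duplicate visit_id")

  expect_error(event_log(toy_log()[, -1], "T", "walkin"), "missing required column")
})

test_that("walk-in proxy sets scheduled time to arrival at ingest", {
  rows <- visit_row("W", "2018-03-01T09:07", "2018-03-01T09:30",
                    "2018-03-01T09:40", sch = "2018-03-01T10:00")
  log <- event_log(rows, "T", "walkin")
  expect_equal(log$scheduled_time, log$arrival_time)
  sched <- event_log(rows, "T", "scheduled")
  expect_equal(sched$scheduled_time, ts("2018-03-01T10:00"))
})

test_that("write/read round trip is the identity on valid logs", {
  log <- toy_log()
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, path)
  back <- read_event_log(path, "walkin")
  expect_equal(as.data.frame(back), as.data.frame(log))
  expect_equal(attr(back, "facility_type"), "walkin")

  # richer round trip out of the simulator, with NA optional fields
  sim <- simulate_facility(facility_config(
    "RT", "hybrid", n_servers = 2, walkin_rate = 3, booked_per_slot = 0.8,
    n_days = 3, seed = 5))
  write_event_log(sim$log, path)
  back2 <- read_event_log(path, "hybrid")
  expect_equal(as.data.frame(back2), as.data.frame(sim$log))

  # empty log -> header-only file
  empty <- event_log(toy_log()[0, ], "T", "walkin")
  write_event_log(empty, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_event_log(path, "walkin")), 0L)
})

test_that("read_event_log reports schema and parse problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("visit_id,facility_id", path)
  expect_error(read_event_log(path, "walkin"), "missing required column")

  log <- toy_log()
  df <- as.data.frame(log)
  df$begin_time <- format(df$begin_time, "%d/%m/%Y %H:%M")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_event_log(path, "walkin"), "unparseable timestamp")
})

test_that("targets follow the delay/wait definitions", {
  row <- visit_row("D", "2018-03-01T09:55", "2018-03-01T10:25",
                   "2018-03-01T10:45", sch = "2018-03-01T10:00")
  sched <- event_log(row, "T", "scheduled")
  expect_equal(compute_target(sched), 25)  # begin - scheduled

  early <- visit_row("E", "2018-03-01T09:40", "2018-03-01T09:50",
                     "2018-03-01T10:10", sch = "2018-03-01T10:00")
  expect_equal(compute_target(event_log(early, "T", "scheduled")), -10)

  boundary <- visit_row("F", "2018-03-01T10:00", "2018-03-01T10:00",
                        "2018-03-01T10:10")
  expect_equal(compute_target(event_log(boundary, "T", "walkin")), 0)

  # walk-in targets are nonnegative on every valid log
  wl <- random_small_log(3, "walkin")
  expect_true(all(compute_target(wl) >= 0))

  noscHed <- as.data.frame(sched)
  noscHed$scheduled_time <- as.POSIXct(NA)
  expect_error(
    compute_target(structure(noscHed, facility_type = "scheduled",
                             class = c("event_log", "data.frame"))),
    "missing scheduled_time")
})

test_that("log summaries report volume and nonnegative walk-in waits", {
  one <- event_log(visit_row("G", "2018-03-01T09:00", "2018-03-01T09:25",
                             "2018-03-01T09:35"), "T", "walkin")
  s <- summary(one)
  expect_equal(s$mean_target, 25)
  expect_equal(s$visits_per_day, 1)

  sim <- simulate_facility(facility_presets(n_days = 10, seed = 2)$F4)
  s4 <- summary(sim$log)
  expect_true(s4$mean_target >= 0)
  expect_equal(s4$visits_per_day, nrow(sim$log) / s4$n_days)

  expect_error(summary(event_log(toy_log()[0, ], "T", "walkin")), "empty")
})
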