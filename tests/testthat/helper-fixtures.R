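# Fixture builders: tiny hand-specified logs, random small simulated logs and
# planted-signal feature matrices.  Everything is generated in code.

ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

# A visit-row builder with sensible defaults.
visit_row <- function(id, arr, beg, end, sch = arr, code = "EX-A",
                      category = "neuro", contrast = "none", resource = "R01",
                      age = 50, outpatient = TRUE, addon = NA) {
  data.frame(
    visit_id = id, facility_id = "T", exam_code = code,
    exam_category = category, contrast_flag = contrast,
    scheduled_time = sch, arrival_time = arr, begin_time = beg,
    end_time = end, resource_id = resource, patient_age = age,
    is_outpatient = outpatient, addon_time = addon,
    stringsAsFactors = FALSE
  )
}

# The three-visit toy log: A arr 09:00 beg 09:20, B arr 09:05 beg 09:30,
# C arr 09:15 beg 09:40 (walk-in, one day).
toy_log <- function() {
  rows <- rbind(
    visit_row("A", "2018-03-01T09:00", "2018-03-01T09:20", "2018-03-01T09:50"),
    visit_row("B", "2018-03-01T09:05", "2018-03-01T09:30", "2018-03-01T09:55"),
    visit_row("C", "2018-03-01T09:15", "2018-03-01T09:40", "2018-03-01T10:00")
  )
  event_log(rows, facility_id = "T", facility_type = "walkin")
}

toy_profile <- function(log, ...) {
  facility_profile(log, reference_days = 400, slot_minutes = 30,
                   n_servers = 1, ...)
}

# A small one-day random simulated log (walk-in or scheduled), for oracle
# sweeps.
random_small_log <- function(seed, type = c("walkin", "scheduled", "hybrid")) {
  type <- match.arg(type)
  cfg <- facility_config(
    paste0("S", seed), type,
    open_hour = 8, close_hour = 12, slot_minutes = 30,
    n_servers = sample(1:2, 1),
    exam_mix = default_exam_mix(sample(8:18, 1)),
    booked_per_slot = if (type == "walkin") 0 else runif(1, 0.5, 1.5),
    walkin_rate = if (type == "scheduled") 0 else runif(1, 2, 5),
    noshow_prob = 0.1, addon_prob = if (type == "walkin") 0 else 0.2,
    n_days = 1, seed = seed
  )
  simulate_facility(cfg)$log
}

# Feature-matrix shaped frame with planted linear signal in f1 (and optional
# extra signal features), remaining columns independent noise.
planted_matrix <- function(n, p = 10, beta = c(f1 = 2), noise_sd = 1,
                           seed = 1, span_days = 250) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- drop(X[, names(beta), drop = FALSE] %*% beta) + rnorm(n, 0, noise_sd)
    df <- data.frame(visit_id = sprintf("v%05d", seq_len(n)),
                     stringsAsFactors = FALSE)
    day_idx <- sort(sample.int(span_days, n, replace = TRUE)) - 1L
    df$prediction_time <- ts("2018-01-01T09:00") + day_idx * 86400 +
      round(runif(n, 0, 400)) * 60
    df <- cbind(df, as.data.frame(X))
    df$target <- y
    class(df) <- c("feature_matrix", "data.frame")
    df
  })
}

# Simulated scheduled facility -> feature matrix (shared across expensive
# tests; memoised per R session).
sim_feature_matrix <- local({
  cache <- list()
  function(preset = "F2", n_days = 230, seed = 11) {
    key <- paste(preset, n_days, seed)
    if (is.null(cache[[key]])) {
      cfg <- facility_presets(n_days = n_days, seed = seed)[[preset]]
      sim <- simulate_facility(cfg)
      prof <- facility_profile(sim$log, slot_minutes = cfg$slot_minutes,
                               n_servers = cfg$n_servers)
      cache[[key]] <<- featurize_log(sim$log, feature_catalog(), prof)
    }
    cache[[key]]
  }
})

# quiet feature_set builder for synthetic f1..fp columns
fs <- function(x, source) suppressWarnings(feature_set(x, source))
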