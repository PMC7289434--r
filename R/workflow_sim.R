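#' Facility simulation configuration
#'
#' Describes one outpatient imaging facility for the discrete-event simulator:
#' its service discipline (scheduled, hybrid or walk-in), operating hours,
#' appointment grid, server (scanner/room) count, exam mix, patient earliness
#' behaviour, walk-in arrival rate, no-show and add-on rates.
#'
#' @param facility_id single string, e.g. `"F1"`.
#' @param facility_type `"scheduled"` (appointments only, queue served by
#'   scheduled order — not FIFO with respect to arrival), `"hybrid"`
#'   (appointments plus interspersed walk-ins) or `"walkin"` (FIFO by
#'   arrival).
#' @param open_hour,close_hour daily operating window, fractional hours
#'   (default 8–17).
#' @param slot_minutes appointment-grid step in minutes; must divide the
#'   operating window.
#' @param n_servers number of parallel servers (scanners); `>= 1`.
#' @param exam_mix data.frame with columns `exam_code`, `prob`,
#'   `mean_minutes`, `sdlog` (log-normal dispersion), `category`
#'   (exam body-region category or `"combined"`), `contrast` (`"none"`,
#'   `"with"`, `"with_and_without"`).  `prob` must sum to 1.
#' @param booked_per_slot mean number of booked appointments per slot
#'   (Poisson); scheduled demand. Ignored for walk-in facilities.
#' @param earliness_mean,earliness_sd normal model for
#'   `scheduled_time - arrival_time` offsets: mean -20 means patients arrive
#'   on average 20 minutes early.
#' @param walkin_rate mean walk-in arrivals per hour (walk-in and hybrid
#'   facilities; 0 otherwise).
#' @param noshow_prob probability a booked patient never arrives (the visit is
#'   dropped).
#' @param addon_prob probability, per slot, that an extra patient is added to
#'   the schedule during the day; add-ons carry a schedule timestamp equal to
#'   their insertion time and are flagged via `addon_time`.
#' @param n_days number of simulated operating days.
#' @param start_date first simulated calendar day.
#' @param mean_age,sd_age patient-age model (years).
#' @param outpatient_prob probability a visit is an outpatient visit.
#' @param seed integer seed; with the same config this makes the simulated log
#'   byte-identical across runs.
#'
#' @return An object of class `facility_config`.
#' @seealso [simulate_facility()], [facility_presets()]
#' @export
facility_config <- function(facility_id,
                            facility_type = c("scheduled", "hybrid", "walkin"),
                            open_hour = 8, close_hour = 17,
                            slot_minutes = 30,
                            n_servers = 2,
                            exam_mix = default_exam_mix(),
                            booked_per_slot = 1,
                            earliness_mean = -20, earliness_sd = 10,
                            walkin_rate = 0,
                            noshow_prob = 0.05,
                            addon_prob = 0.05,
                            n_days = 250,
                            start_date = "2018-01-01",
                            mean_age = 55, sd_age = 18,
                            outpatient_prob = 0.8,
                            seed = 1L) {
  facility_type <- match.arg(facility_type)
  if (!is_count(n_days)) stopf("facility_config: n_days must be a positive integer")
  if (!is_count(n_servers)) stopf("facility_config: n_servers must be a positive integer")
  if (!is_count(slot_minutes)) stopf("facility_config: slot_minutes must be a positive integer")
  window <- (close_hour - open_hour) * 60
  if (window <= 0) stopf("facility_config: close_hour must be after open_hour")
  if (window %% slot_minutes != 0) {
    stopf("facility_config: slot_minutes (%d) must divide the %g-minute operating window",
          slot_minutes, window)
  }
  exam_mix <- as.data.frame(exam_mix, stringsAsFactors = FALSE)
  stopifnot(all(c("exam_code", "prob", "mean_minutes", "sdlog",
                  "category", "contrast") %in% names(exam_mix)))
  if (abs(sum(exam_mix$prob) - 1) > 1e-8) {
    stopf("facility_config: exam_mix probabilities must sum to 1")
  }
  if (any(exam_mix$mean_minutes <= 0)) {
    stopf("facility_config: exam mean_minutes must be positive")
  }
  if (noshow_prob < 0 || noshow_prob > 1 || addon_prob < 0 || addon_prob > 1) {
    stopf("facility_config: probabilities must lie in [0, 1]")
  }
  if (facility_type == "walkin" && walkin_rate < 0) {
    stopf("facility_config: walkin_rate must be nonnegative")
  }
  structure(list(
    facility_id = facility_id, facility_type = facility_type,
    open_hour = open_hour, close_hour = close_hour,
    slot_minutes = as.integer(slot_minutes), n_servers = as.integer(n_servers),
    exam_mix = exam_mix, booked_per_slot = booked_per_slot,
    earliness_mean = earliness_mean, earliness_sd = earliness_sd,
    walkin_rate = walkin_rate, noshow_prob = noshow_prob,
    addon_prob = addon_prob, n_days = as.integer(n_days),
    start_date = as.Date(start_date),
    mean_age = mean_age, sd_age = sd_age,
    outpatient_prob = outpatient_prob,
    seed = as.integer(seed)
  ), class = "facility_config")
}

#' @export
print.facility_config <- function(x, ...) {
  cat(sprintf(
    "<facility_config> %s (%s): %d servers, %02.0f:00-%02.0f:00, slot %d min, %d days, seed %d\n",
    x$facility_id, x$facility_type, x$n_servers, x$open_hour, x$close_hour,
    x$slot_minutes, x$n_days, x$seed))
  invisible(x)
}

#' Default exam mix used by the simulator
#'
#' A generic single-modality mix with body-region categories, contrast flags
#' and log-normal service-time parameters.  Within one modality protocol
#' durations are standardized, so the per-category means differ only
#' modestly; the rare combined multi-exam code (excluded from per-region
#' line counts) is the one genuinely long protocol.
#'
#' @param mean_minutes overall scale of mean service times.
#' @return data.frame usable as `exam_mix` in [facility_config()].
#' @export
default_exam_mix <- function(mean_minutes = 30) {
  m <- mean_minutes / 30
  data.frame(
    exam_code = c("EX-MSK", "EX-CARD", "EX-VASC", "EX-ABD", "EX-NEURO",
                  "EX-PED", "EX-THOR", "EX-OTH", "EX-COMBO"),
    prob = c(0.20, 0.08, 0.07, 0.20, 0.15, 0.05, 0.10, 0.10, 0.05),
    mean_minutes = m * c(30, 33, 32, 30, 32, 28, 30, 28, 52),
    sdlog = c(0.30, 0.35, 0.35, 0.30, 0.30, 0.35, 0.30, 0.40, 0.30),
    category = c("MSK", "cardiac", "vascular", "abdominal", "neuro",
                 "pediatric", "thoracic", "other", "combined"),
    contrast = c("none", "with", "with_and_without", "with", "none",
                 "none", "with", "none", "with_and_without"),
    stringsAsFactors = FALSE
  )
}

#' Facility archetype presets
#'
#' Four archetypes emulating differently organised outpatient imaging
#' facilities: `F1` (MRI-like, fully scheduled, long exams, ~25 visits/day),
#' `F2` (ultrasound-like, fully scheduled, ~55 visits/day), `F3` (CT-like,
#' mostly scheduled with interspersed walk-ins, ~50 visits/day) and `F4`
#' (X-ray-like, walk-in only FIFO, ~115 visits/day, short exams).  Volumes
#' span the 25–120 visits/day operating range typical of such sites.
#'
#' @param n_days simulated days per facility.
#' @param seed base seed; facility k uses `seed + k`.
#' @return Named list of [facility_config()] objects.
#' @export
facility_presets <- function(n_days = 250, seed = 1L) {
  list(
    F1 = facility_config("F1", "scheduled", slot_minutes = 60, n_servers = 2,
                         exam_mix = default_exam_mix(42),
                         booked_per_slot = 2.65, n_days = n_days,
                         seed = seed + 1L),
    F2 = facility_config("F2", "scheduled", slot_minutes = 30, n_servers = 4,
                         exam_mix = default_exam_mix(26),
                         booked_per_slot = 3.2, n_days = n_days,
                         seed = seed + 2L),
    F3 = facility_config("F3", "hybrid", slot_minutes = 30, n_servers = 3,
                         exam_mix = default_exam_mix(20),
                         booked_per_slot = 1.25, walkin_rate = 2.5,
                         n_days = n_days, seed = seed + 3L),
    F4 = facility_config("F4", "walkin", slot_minutes = 30, n_servers = 3,
                         exam_mix = default_exam_mix(9),
                         booked_per_slot = 0, walkin_rate = 12,
                         noshow_prob = 0, addon_prob = 0,
                         n_days = n_days, seed = seed + 4L)
  )
}

#' Simulate a facility event log
#'
#' Discrete-event simulation at one-minute clock granularity.  Scheduled
#' patients are booked on the slot grid with normally distributed earliness
#' offsets and log-normal service times; walk-ins arrive as a Poisson process
#' with their arrival standing in for a scheduled time.  The next free server
#' takes the waiting patient with the earliest scheduled time among those
#' already arrived (so scheduled queues are not FIFO with respect to arrival,
#' while walk-in queues are), and a scheduled exam never begins before its
#' scheduled time.  Congestion therefore propagates delays exactly as in a
#' multi-server queue.
#'
#' @param config a [facility_config()].
#' @return A list with components `log` (an [event_log()]) and `truth`
#'   (a `simulation_truth`: latent service durations, queue-entry order and
#'   per-server busy intervals, for oracle checks).
#' @examples
#' cfg <- facility_config("toy", "walkin", n_servers = 1, walkin_rate = 4,
#'                        n_days = 2, noshow_prob = 0, addon_prob = 0, seed = 7)
#' sim <- simulate_facility(cfg)
#' summary(sim$log)
#' @export
simulate_facility <- function(config) {
  stopifnot(inherits(config, "facility_config"))
  withr::with_seed(config$seed, simulate_facility_impl(config))
}

simulate_facility_impl <- function(cfg) {
  all_days <- vector("list", cfg$n_days)
  truth_days <- vector("list", cfg$n_days)
  counter <- 0L
  for (d in seq_len(cfg$n_days)) {
    day <- simulate_day(cfg, cfg$start_date + (d - 1L))
    if (!nrow(day$visits)) next
    day$visits$visit_id <- sprintf("%s-%06d", cfg$facility_id,
                                   counter + seq_len(nrow(day$visits)))
    counter <- counter + nrow(day$visits)
    all_days[[d]] <- day$visits
    truth_days[[d]] <- day$truth
  }
  visits <- do.call(rbind, all_days)
  if (is.null(visits)) {
    visits <- empty_visit_frame()
  }
  log <- event_log(visits, facility_id = cfg$facility_id,
                   facility_type = cfg$facility_type)
  truth <- do.call(rbind, truth_days)
  structure(list(log = log, truth = truth,
                 config = cfg), class = "facility_sim")
}

empty_visit_frame <- function() {
  df <- data.frame(
    visit_id = character(0), facility_id = character(0),
    exam_code = character(0), exam_category = character(0),
    contrast_flag = character(0), stringsAsFactors = FALSE
  )
  now <- as.POSIXct(character(0), tz = "UTC")
  df$scheduled_time <- now; df$arrival_time <- now
  df$begin_time <- now; df$end_time <- now
  df$resource_id <- character(0); df$patient_age <- numeric(0)
  df$is_outpatient <- logical(0)
  df$addon_time <- now
  df
}

# One operating day: demand generation + queue simulation.
simulate_day <- function(cfg, date) {
  day0 <- as.POSIXct(paste0(format(date), "T00:00"),
                     format = TS_FORMAT, tz = "UTC")
  open_min <- cfg$open_hour * 60
  close_min <- cfg$close_hour * 60
  grid <- seq(open_min, close_min - cfg$slot_minutes, by = cfg$slot_minutes)

  sched <- arr <- addon <- numeric(0)  # minutes after midnight
  is_addon <- logical(0)

  if (cfg$facility_type != "walkin" && cfg$booked_per_slot > 0) {
    n_per_slot <- stats::rpois(length(grid), cfg$booked_per_slot)
    s <- rep(grid, n_per_slot)
    early <- stats::rnorm(length(s), cfg$earliness_mean, cfg$earliness_sd)
    a <- pmin(pmax(round(s + early), 0), close_min)
    keep <- stats::runif(length(s)) >= cfg$noshow_prob
    sched <- s[keep]; arr <- a[keep]
    addon <- rep(NA_real_, length(sched)); is_addon <- rep(FALSE, length(sched))
  }

  if (cfg$facility_type != "walkin" && cfg$addon_prob > 0) {
    add_slots <- grid[stats::runif(length(grid)) < cfg$addon_prob]
    if (length(add_slots)) {
      t_ins <- round(add_slots + stats::runif(length(add_slots), 0, cfg$slot_minutes))
      sched <- c(sched, t_ins); arr <- c(arr, t_ins)
      addon <- c(addon, t_ins); is_addon <- c(is_addon, rep(TRUE, length(t_ins)))
    }
  }

  if (cfg$facility_type != "scheduled" && cfg$walkin_rate > 0) {
    n_w <- stats::rpois(1L, cfg$walkin_rate * (close_min - open_min) / 60)
    if (n_w > 0) {
      a <- sort(round(stats::runif(n_w, open_min, close_min)))
      sched <- c(sched, a)  # walk-in proxy: scheduled = arrival
      arr <- c(arr, a)
      addon <- c(addon, rep(NA_real_, n_w))
      is_addon <- c(is_addon, rep(FALSE, n_w))
    }
  }

  n <- length(arr)
  if (!n) {
    return(list(visits = empty_visit_frame()[0, ], truth = NULL))
  }

  exam_idx <- sample.int(nrow(cfg$exam_mix), n, replace = TRUE,
                         prob = cfg$exam_mix$prob)
  mu <- cfg$exam_mix$mean_minutes[exam_idx]
  sdl <- cfg$exam_mix$sdlog[exam_idx]
  dur <- pmax(1, round(stats::rlnorm(n, log(mu) - sdl^2 / 2, sdl)))

  q <- run_queue(arr, sched, dur, cfg$n_servers)

  visits <- data.frame(
    visit_id = NA_character_,
    facility_id = cfg$facility_id,
    exam_code = cfg$exam_mix$exam_code[exam_idx],
    exam_category = cfg$exam_mix$category[exam_idx],
    contrast_flag = cfg$exam_mix$contrast[exam_idx],
    stringsAsFactors = FALSE
  )
  visits$scheduled_time <- day0 + sched * 60
  visits$arrival_time <- day0 + arr * 60
  visits$begin_time <- day0 + q$begin * 60
  visits$end_time <- day0 + q$end * 60
  visits$resource_id <- sprintf("R%02d", q$server)
  visits$patient_age <- pmax(0, round(stats::rnorm(n, cfg$mean_age, cfg$sd_age)))
  visits$is_outpatient <- stats::runif(n) < cfg$outpatient_prob
  visits$addon_time <- day0 + addon * 60  # NA stays NA

  truth <- data.frame(
    date = date,
    service_minutes = dur,
    queue_position = q$position,
    server = q$server,
    busy_start = as.numeric(visits$begin_time),
    busy_end = as.numeric(visits$end_time)
  )
  list(visits = visits, truth = truth)
}

# Multi-server queue core.  A patient is eligible once arrived AND past their
# scheduled time (walk-ins have scheduled == arrival, so eligibility is
# arrival); the next begin event always uses the earliest-free server and the
# eligible patient with the earliest scheduled time (ties: arrival, then
# index).  All times are minutes after midnight.
run_queue <- function(arr, sched, dur, n_servers) {
  n <- length(arr)
  ready <- pmax(arr, sched)
  begin <- end <- rep(NA_real_, n)
  server <- position <- rep(NA_integer_, n)
  free <- rep(-Inf, n_servers)
  pending <- rep(TRUE, n)
  for (k in seq_len(n)) {
    s <- which.min(free)
    tf <- free[s]
    idx <- which(pending)
    start_if <- pmax(tf, ready[idx])
    t_next <- min(start_if)
    elig <- idx[start_if <= t_next]
    j <- elig[order(sched[elig], arr[elig], elig)][1L]
    begin[j] <- max(tf, ready[j])
    end[j] <- begin[j] + dur[j]
    free[s] <- end[j]
    server[j] <- s
    position[j] <- k
    pending[j] <- FALSE
  }
  list(begin = begin, end = end, server = server, position = position)
}

#' @export
print.facility_sim <- function(x, ...) {
  cat(sprintf("<facility_sim> %s: %d visits over %d days\n",
              x$config$facility_id, nrow(x$log), x$config$n_days))
  invisible(x)
}

#' Verify server-capacity consistency of a simulation
#'
#' Checks, against the simulation ground truth, that within each operating
#' day busy intervals never overlap on the same server (so at any instant at
#' most `n_servers` exams are in progress and each begun visit occupies
#' exactly one server).  Operating days are independent: overnight state is
#' not carried over.
#'
#' @param sim result of [simulate_facility()].
#' @return `TRUE` invisibly; errors on violation.
#' @export
check_capacity <- function(sim) {
  truth <- sim$truth
  if (is.null(truth) || !nrow(truth)) return(invisible(TRUE))
  for (grp in split(truth, list(truth$date, truth$server), drop = TRUE)) {
    iv <- grp[order(grp$busy_start), c("busy_start", "busy_end"), drop = FALSE]
    if (nrow(iv) > 1 && any(iv$busy_start[-1] < iv$busy_end[-nrow(iv)])) {
      stopf("server %s has overlapping busy intervals on %s",
            grp$server[1L], grp$date[1L])
    }
  }
  invisible(TRUE)
}
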