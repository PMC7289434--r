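# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
NULL

TS_FORMAT <- "%Y-%m-%dT%H:%M"

# All timestamps live in UTC at minute resolution; durations are numeric
# minutes.  UTC avoids daylight-saving discontinuities inside a simulated
# operating day.
parse_ts <- function(x) {
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable timestamp(s): ", paste(utils::head(x[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  out
}

format_ts <- function(x) {
  out <- format(x, format = TS_FORMAT, tz = "UTC")
  out[is.na(x)] <- ""
  out
}

# Signed difference in minutes (a - b).
mins_between <- function(a, b) {
  as.numeric(difftime(a, b, units = "mins"))
}

# Calendar day (Date, UTC) of a timestamp.
ts_day <- function(x) as.Date(x, tz = "UTC")

# Minutes after local midnight.
minute_of_day <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour * 60 + lt$min
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
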