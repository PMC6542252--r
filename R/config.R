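# Algorithm configuration and time helpers.

#' Algorithm configuration
#'
#' Bundles the thresholds of the sleep-detection algorithm. Clock times are
#' given as `"HH:MM"` or `"HH:MM:SS"` strings and stored as seconds since
#' midnight. The nightly sleep window runs from `window_start` on the evening
#' to `window_end` on the following morning (it must cross midnight); the scan
#' window bounds how far the resumption rule may trace an episode's original
#' boundaries (by default noon to the following noon).
#'
#' @param reactive_lookback seconds before a screen-on in which a notification
#'   marks the episode as reactive. Default 60 s ("within 1 min").
#' @param flood_threshold notifications per app per calendar day above which
#'   that app's notifications are excluded for the day (strictly more than;
#'   default 500).
#' @param window_start,window_end clock-time bounds of the nightly sleep
#'   window, default `"22:00"` to `"10:00"` next day.
#' @param scan_start,scan_end clock-time bounds of the nightly candidate scan,
#'   default `"12:00"` to `"12:00"` next day.
#' @param tz time zone in which all timestamps are interpreted (one zone per
#'   participant; default `"UTC"`).
#' @param exclude_first_last drop nights whose scan window touches the first
#'   or last calendar day of the log (incomplete days). Default `TRUE`.
#' @param short_sleep_floor seconds; detected records shorter than this are
#'   flagged as suspiciously short (naps / shift work are out of scope).
#'   Default 3 hours.
#' @param weekend_basis which date decides whether a night is a weekend night:
#'   `"wake_date"` (wake morning falls on Saturday/Sunday, the default, i.e.
#'   Fri-Sat and Sat-Sun nights) or `"onset_date"` (evening falls on
#'   Saturday/Sunday).
#' @param strict fail on malformed input rows instead of repairing and
#'   logging.
#' @return an object of class `rhythm_config` (a named list).
#' @export
#' @examples
#' cfg <- rhythm_config()
#' cfg$flood_threshold
rhythm_config <- function(reactive_lookback = 60,
                          flood_threshold = 500,
                          window_start = "22:00",
                          window_end = "10:00",
                          scan_start = "12:00",
                          scan_end = "12:00",
                          tz = "UTC",
                          exclude_first_last = TRUE,
                          short_sleep_floor = 3 * 3600,
                          weekend_basis = c("wake_date", "onset_date"),
                          strict = FALSE) {
  weekend_basis <- match.arg(weekend_basis)
  cfg <- list(
    reactive_lookback = as.numeric(reactive_lookback),
    flood_threshold = as.numeric(flood_threshold),
    window_start = clock_seconds(window_start),
    window_end = clock_seconds(window_end),
    scan_start = clock_seconds(scan_start),
    scan_end = clock_seconds(scan_end),
    tz = tz,
    exclude_first_last = isTRUE(exclude_first_last),
    short_sleep_floor = as.numeric(short_sleep_floor),
    weekend_basis = weekend_basis,
    strict = isTRUE(strict)
  )
  validate_rhythm_config(cfg)
  class(cfg) <- "rhythm_config"
  cfg
}

validate_rhythm_config <- function(cfg) {
  if (!is.finite(cfg$reactive_lookback) || cfg$reactive_lookback <= 0)
    stop(rk_config_error("reactive_lookback must be > 0"))
  if (!is.finite(cfg$flood_threshold) || cfg$flood_threshold < 1)
    stop(rk_config_error("flood_threshold must be >= 1"))
  # the sleep window must cross midnight (evening start, morning end)
  if (cfg$window_start <= cfg$window_end)
    stop(rk_config_error(
      "window_start must be a later clock time than window_end (overnight window)"))
  if (!cfg$tz %in% c("UTC", OlsonNames()))
    stop(rk_config_error(sprintf("unknown time zone '%s'", cfg$tz)))
  invisible(cfg)
}

#' @export
print.rhythm_config <- function(x, ...) {
  cat("Sleep-detection configuration\n")
  cat(sprintf("  reactive lookback : %g s\n", x$reactive_lookback))
  cat(sprintf("  flood threshold   : > %g notifications/app/day\n",
              x$flood_threshold))
  cat(sprintf("  sleep window      : %s -> %s (+1d)\n",
              seconds_clock(x$window_start), seconds_clock(x$window_end)))
  cat(sprintf("  scan window       : %s -> %s (+1d)\n",
              seconds_clock(x$scan_start), seconds_clock(x$scan_end)))
  cat(sprintf("  time zone         : %s\n", x$tz))
  cat(sprintf("  first/last day excluded: %s;  short-sleep floor: %g h\n",
              x$exclude_first_last, x$short_sleep_floor / 3600))
  cat(sprintf("  weekend basis     : %s;  strict parsing: %s\n",
              x$weekend_basis, x$strict))
  invisible(x)
}

# ---- structured conditions ---------------------------------------------

rk_error <- function(msg, class) {
  structure(class = c(class, "rk_error", "error", "condition"),
            list(message = msg, call = NULL))
}
rk_input_error <- function(msg) rk_error(msg, "rk_input_error")
rk_config_error <- function(msg) rk_error(msg, "rk_config_error")

# ---- clock/time helpers -------------------------------------------------

# "HH:MM[:SS]" -> seconds since midnight
clock_seconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  p <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!length(p) %in% 2:3 || anyNA(suppressWarnings(as.numeric(p))))
    stop(rk_config_error(sprintf("cannot parse clock time '%s'", x)))
  p <- as.numeric(p)
  p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
}

seconds_clock <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# midnight (00:00) of a Date in a zone, as POSIXct
midnight_of <- function(date, tz) {
  as.POSIXct(paste(format(date), "00:00:00"), tz = tz)
}

# clock seconds on a date -> POSIXct
at_clock <- function(date, secs, tz) {
  midnight_of(date, tz) + secs
}

# seconds elapsed since midnight of `wake_date` (negative before midnight);
# the Table-style scale on which all indicator arithmetic is done
elapsed_since_midnight <- function(time, wake_date, tz) {
  as.numeric(difftime(time, midnight_of(wake_date, tz), units = "secs"))
}

is_weekend_date <- function(date) {
  format(as.Date(date), "%u") %in% c("6", "7")
}
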