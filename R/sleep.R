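# Nightly sleep detection: dummy-boundary labelling, maximal non-usage
# episode selection, resumption of original timestamps; the sleep_series
# estimator and its methods.

#' Label dummy boundaries on a night's non-usage episodes
#'
#' For the night beginning on the evening of `night`, the sleep window runs
#' from `window_start` (22:00) on `night` to `window_end` (10:00) on the next
#' morning. Episodes entirely outside the window are dropped. An episode whose
#' start precedes the window gets a dummy screen-off at window start (the
#' original kept in `original_start`); symmetrically a dummy screen-on at
#' window end for episodes running past it.
#'
#' @param episodes non-usage `data.frame` from [build_nonusage_episodes()].
#' @param night the evening's calendar date (a `Date`).
#' @param cfg a [rhythm_config()].
#' @return the labelled `data.frame` (possibly with fewer rows).
#' @export
label_dummy_boundaries <- function(episodes, night, cfg = rhythm_config()) {
  night <- as.Date(night)
  w0 <- at_clock(night, cfg$window_start, cfg$tz)
  w1 <- at_clock(night + 1, cfg$window_end, cfg$tz)
  keep <- as.numeric(episodes$end) > as.numeric(w0) &
    as.numeric(episodes$start) < as.numeric(w1)
  ep <- episodes[keep, , drop = FALSE]
  if (!nrow(ep)) return(ep)
  early <- as.numeric(ep$start) < as.numeric(w0)
  ep$start[early] <- w0
  ep$start_is_dummy[early] <- TRUE
  late <- as.numeric(ep$end) > as.numeric(w1)
  ep$end[late] <- w1
  ep$end_is_dummy[late] <- TRUE
  rownames(ep) <- NULL
  ep
}

#' Midpoint of sleep
#'
#' Clock time halfway between sleep onset and wake, rounded to the whole
#' second (half up), matching the 1-second resolution of the event stream.
#'
#' @param onset,wake POSIXct, `onset < wake`.
#' @return POSIXct midpoint.
#' @export
#' @examples
#' midpoint_of(as.POSIXct("2018-03-02 23:00:00", tz = "UTC"),
#'             as.POSIXct("2018-03-03 06:00:00", tz = "UTC"))
midpoint_of <- function(onset, wake) {
  o <- as.numeric(onset); w <- as.numeric(wake)
  if (any(o >= w)) stop(rk_input_error("midpoint_of: onset must precede wake"))
  as.POSIXct(floor(o + (w - o) / 2 + 0.5), origin = "1970-01-01",
             tz = attr(onset, "tzone") %||% "UTC")
}

#' Detect one night's sleep
#'
#' Implements the maximal non-usage rule for the night waking on `wake_date`:
#' candidate episodes are the non-usage episodes contained in the scan window
#' (noon on the previous day to noon on `wake_date` by default); after dummy
#' labelling the episode with maximal duration is sleep. If the winner starts
#' (ends) at a dummy boundary, the original screen-off (screen-on) is resumed
#' as sleep onset (wake time), flagged `onset_extended` (`wake_extended`).
#' Ties in maximal duration go to the earliest-starting episode and are
#' flagged.
#'
#' @param episodes non-usage `data.frame` (a full series is fine; the night's
#'   candidates are selected internally).
#' @param wake_date the morning's calendar date (a `Date`).
#' @param cfg a [rhythm_config()].
#' @return a one-row `data.frame` (`wake_date`, `onset`, `wake`, `midpoint`,
#'   `tst`, `onset_extended`, `wake_extended`, `n_candidates`, `tie`,
#'   `short_sleep`) or `NULL` for a missing night.
#' @export
detect_sleep <- function(episodes, wake_date, cfg = rhythm_config()) {
  wake_date <- as.Date(wake_date)
  night <- wake_date - 1
  s0 <- as.numeric(at_clock(night, cfg$scan_start, cfg$tz))
  s1 <- as.numeric(at_clock(wake_date, cfg$scan_end, cfg$tz))
  cand <- episodes[as.numeric(episodes$start) >= s0 &
                     as.numeric(episodes$end) <= s1, , drop = FALSE]
  lab <- label_dummy_boundaries(cand, night, cfg)
  if (!nrow(lab)) return(NULL)
  dur <- as.numeric(lab$end) - as.numeric(lab$start)
  best <- max(dur)
  ties <- which(dur == best)
  tie <- length(ties) > 1
  if (tie)
    message(sprintf("detect_sleep %s: %d equal-duration maximal episodes; using earliest",
                    format(wake_date), length(ties)))
  win <- lab[ties[which.min(as.numeric(lab$start[ties]))], ]
  onset <- if (win$start_is_dummy) win$original_start else win$start
  wake <- if (win$end_is_dummy) win$original_end else win$end
  tst <- as.numeric(wake) - as.numeric(onset)
  data.frame(wake_date = wake_date, onset = onset, wake = wake,
             midpoint = midpoint_of(onset, wake), tst = tst,
             onset_extended = win$start_is_dummy,
             wake_extended = win$end_is_dummy,
             n_candidates = nrow(lab), tie = tie,
             short_sleep = tst < cfg$short_sleep_floor)
}

#' Infer a multi-night sleep series from a raw event log
#'
#' The core estimator. Runs the full pipeline on one participant's event
#' stream: deterministic sorting, notification-flood exclusion, usage-episode
#' construction (with glitch repair), proactive/reactive classification,
#' non-usage episodes between proactive sessions, and nightly maximal
#' non-usage detection with dummy boundaries and resumption. One record (or an
#' explicit missing-night entry) per night in the log span; nights touching
#' the incomplete first and last calendar days are excluded by default.
#'
#' @param events event `data.frame` (from [read_event_log()] or
#'   [simulate_participant()]).
#' @param participant_id identifier attached to the series.
#' @param cfg a [rhythm_config()].
#' @return an object of class `sleep_series`: a list with `participant_id`,
#'   `records` (data frame of nightly indicators), `missing_nights` (Date
#'   vector), `source`, `config`, and bookkeeping counts.
#' @export
#' @examples
#' sim <- simulate_participant(sim_params(n_days = 4, seed = 7), 1)
#' fit <- detect_sleep_series(sim$events, "p01")
#' fit
detect_sleep_series <- function(events, participant_id = "participant",
                                cfg = rhythm_config()) {
  if (!nrow(events)) {
    warning("detect_sleep_series: empty event log")
    return(new_sleep_series(participant_id, empty_records(), as.Date(character()),
                            cfg, 0L, 0L))
  }
  events <- sort_events(events)
  events <- filter_notification_floods(events, cfg)
  usage <- build_usage_episodes(events)
  usage <- classify_proactive(usage, events, cfg)
  gaps <- build_nonusage_episodes(usage)
  dates <- as.Date(format(range(events$timestamp), "%Y-%m-%d", tz = cfg$tz))
  wake_dates <- seq(dates[1] + 1, dates[2], by = "day")
  if (cfg$exclude_first_last)
    wake_dates <- wake_dates[wake_dates - 1 > dates[1] &
                               wake_dates < dates[2]]
  recs <- vector("list", length(wake_dates))
  missing <- logical(length(wake_dates))
  for (i in seq_along(wake_dates)) {
    r <- detect_sleep(gaps, wake_dates[i], cfg)
    if (is.null(r)) missing[i] <- TRUE else recs[[i]] <- r
  }
  records <- if (any(!missing)) do.call(rbind, recs[!missing]) else
    empty_records()
  records <- flag_dst(records, cfg)
  new_sleep_series(participant_id, records, wake_dates[missing], cfg,
                   attr(usage, "n_repairs") %||% 0L,
                   attr(events, "n_flood_removed") %||% 0L)
}

empty_records <- function() {
  z <- as.POSIXct(character())
  data.frame(wake_date = as.Date(character()), onset = z, wake = z,
             midpoint = z, tst = numeric(), onset_extended = logical(),
             wake_extended = logical(), n_candidates = integer(),
             tie = logical(), short_sleep = logical())
}

# flag nights whose scan span crosses a UTC-offset change (DST)
flag_dst <- function(records, cfg) {
  if (!nrow(records)) { records$dst <- logical(0); return(records) }
  off <- function(t) format(t, "%z", tz = cfg$tz)
  records$dst <- off(records$onset) != off(records$wake)
  records
}

new_sleep_series <- function(participant_id, records, missing_nights, cfg,
                             n_repairs, n_flood_removed,
                             source = "app") {
  structure(list(participant_id = as.character(participant_id),
                 records = records,
                 missing_nights = as.Date(missing_nights),
                 source = source, config = cfg,
                 n_repairs = n_repairs,
                 n_flood_removed = n_flood_removed),
            class = "sleep_series")
}

#' Build a sleep series from a self-report diary
#'
#' Wraps one participant's diary rows (one per night: reported onset and wake)
#' in the same `sleep_series` container the detector produces, deriving
#' midpoint and total sleep time, so diary and device records flow through
#' identical downstream statistics.
#'
#' @param diary `data.frame` with columns `onset` and `wake` (POSIXct or
#'   parseable strings).
#' @param participant_id identifier.
#' @param cfg a [rhythm_config()].
#' @return a `sleep_series` with `source = "self_report"`.
#' @export
self_report_series <- function(diary, participant_id = "participant",
                               cfg = rhythm_config()) {
  onset <- if (inherits(diary$onset, "POSIXct")) diary$onset else
    parse_timestamps(as.character(diary$onset), cfg$tz)
  wake <- if (inherits(diary$wake, "POSIXct")) diary$wake else
    parse_timestamps(as.character(diary$wake), cfg$tz)
  if (anyNA(onset) || anyNA(wake))
    stop(rk_input_error("self_report_series: unparseable diary times"))
  if (any(as.numeric(onset) >= as.numeric(wake)))
    stop(rk_input_error("self_report_series: onset must precede wake"))
  tst <- as.numeric(wake) - as.numeric(onset)
  records <- data.frame(
    wake_date = as.Date(format(wake, "%Y-%m-%d", tz = cfg$tz)),
    onset = onset, wake = wake, midpoint = midpoint_of(onset, wake),
    tst = tst, onset_extended = FALSE, wake_extended = FALSE,
    n_candidates = NA_integer_, tie = FALSE,
    short_sleep = tst < cfg$short_sleep_floor)
  records <- records[order(records$wake_date), , drop = FALSE]
  if (anyDuplicated(records$wake_date))
    stop(rk_input_error("self_report_series: duplicate wake_date in diary"))
  records <- flag_dst(records, cfg)
  new_sleep_series(participant_id, records, as.Date(character()), cfg, 0L, 0L,
                   source = "self_report")
}

# ---- methods ------------------------------------------------------------

#' @export
print.sleep_series <- function(x, ...) {
  r <- x$records
  cat(sprintf("Sleep series for '%s' (%s): %d night(s), %d missing\n",
              x$participant_id, x$source, nrow(r), length(x$missing_nights)))
  if (nrow(r)) {
    cat(sprintf("  nights %s .. %s\n", format(min(r$wake_date)),
                format(max(r$wake_date))))
    cat(sprintf("  mean onset %s, wake %s, midpoint %s, TST %.2f h\n",
                mean_clock(r$onset, r$wake_date, x$config),
                mean_clock(r$wake, r$wake_date, x$config),
                mean_clock(r$midpoint, r$wake_date, x$config),
                mean(r$tst) / 3600))
    if (any(r$short_sleep))
      cat(sprintf("  warning: %d night(s) below the %g-h short-sleep floor\n",
                  sum(r$short_sleep), x$config$short_sleep_floor / 3600))
  }
  invisible(x)
}

mean_clock <- function(times, wake_dates, cfg) {
  s <- mean(elapsed_since_midnight(times, wake_dates, cfg$tz))
  seconds_clock(s %% 86400)
}

#' @export
summary.sleep_series <- function(object, ...) {
  r <- object$records
  el <- function(col) elapsed_since_midnight(r[[col]], r$wake_date,
                                             object$config$tz)
  wknd <- is_weekend_night(r$wake_date, r$onset, object$config)
  out <- list(
    participant_id = object$participant_id, source = object$source,
    n_nights = nrow(r), n_missing = length(object$missing_nights),
    n_weekend = sum(wknd),
    indicators = if (nrow(r)) data.frame(
      indicator = c("onset", "wake", "midpoint", "tst"),
      mean_seconds = c(mean(el("onset")), mean(el("wake")),
                       mean(el("midpoint")), mean(r$tst)),
      sd_seconds = c(stats::sd(el("onset")), stats::sd(el("wake")),
                     stats::sd(el("midpoint")), stats::sd(r$tst))
    ) else NULL,
    social_jetlag_min = tryCatch(social_jetlag(object),
                                 error = function(e) NA_real_),
    n_extended = c(onset = sum(r$onset_extended), wake = sum(r$wake_extended)),
    n_repairs = object$n_repairs,
    n_flood_removed = object$n_flood_removed)
  class(out) <- "summary.sleep_series"
  out
}

#' @export
print.summary.sleep_series <- function(x, ...) {
  cat(sprintf("Sleep series '%s' (%s): %d nights (%d weekend), %d missing\n",
              x$participant_id, x$source, x$n_nights, x$n_weekend, x$n_missing))
  if (!is.null(x$indicators)) {
    ind <- x$indicators
    for (i in seq_len(nrow(ind)))
      cat(sprintf("  %-8s mean %s (elapsed %.1f s), sd %.1f s\n",
                  ind$indicator[i], seconds_clock(ind$mean_seconds[i] %% 86400),
                  ind$mean_seconds[i], ind$sd_seconds[i]))
  }
  cat(sprintf("  social jetlag: %.1f min;  extended onset/wake: %d/%d;  repairs: %d;  flood-removed notifications: %d\n",
              x$social_jetlag_min, x$n_extended["onset"], x$n_extended["wake"],
              x$n_repairs, x$n_flood_removed))
  invisible(x)
}

#' @export
as.data.frame.sleep_series <- function(x, ...) {
  r <- x$records
  if (nrow(r)) {
    r$participant_id <- x$participant_id
    r$source <- x$source
    r[c("participant_id", "source", setdiff(names(r),
                                            c("participant_id", "source")))]
  } else r
}

#' Plot the nightly midpoint of sleep
#'
#' Midpoint of sleep (hours after midnight of the wake date) against wake
#' date — the series' circadian-rhythm track.
#'
#' @param x a `sleep_series`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sleep_series <- function(x, ...) {
  r <- x$records
  if (!nrow(r)) { warning("empty sleep series"); return(invisible(x)) }
  m <- elapsed_since_midnight(r$midpoint, r$wake_date, x$config$tz) / 3600
  graphics::plot(r$wake_date, m, type = "b", pch = 19,
                 xlab = "wake date", ylab = "midpoint of sleep (h after midnight)",
                 main = sprintf("Midpoint of sleep: %s (%s)",
                                x$participant_id, x$source), ...)
  invisible(x)
}

is_weekend_night <- function(wake_date, onset, cfg) {
  if (cfg$weekend_basis == "wake_date") is_weekend_date(wake_date)
  else is_weekend_date(as.Date(format(onset, "%Y-%m-%d", tz = cfg$tz)))
}
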