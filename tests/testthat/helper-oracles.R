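# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-element loops, split-apply counting) and share no
# code with the implementation they check.

UTC <- "UTC"

pt <- function(x) as.POSIXct(x, tz = UTC)

# build an event frame from vectors of time strings / POSIXct
ev <- function(on = NULL, off = NULL, notif = NULL, app = "app01") {
  tos <- function(x) if (inherits(x, "POSIXct")) x else pt(x)
  rows <- list()
  if (length(on)) rows <- c(rows, list(data.frame(
    timestamp = tos(on), event_type = "screen_on", app_id = NA_character_)))
  if (length(off)) rows <- c(rows, list(data.frame(
    timestamp = tos(off), event_type = "screen_off", app_id = NA_character_)))
  if (length(notif)) rows <- c(rows, list(data.frame(
    timestamp = tos(notif), event_type = "notification",
    app_id = rep_len(app, length(notif)))))
  sort_events(do.call(rbind, rows))
}

# ---- oracle: flood filter ----------------------------------------------
# group notifications by (app, day) with split(); drop groups over threshold
oracle_flood_filter <- function(events, threshold = 500, tz = UTC) {
  day <- format(events$timestamp, "%Y-%m-%d", tz = tz)
  drop <- rep(FALSE, nrow(events))
  idx <- which(events$event_type == "notification")
  for (g in split(idx, paste(events$app_id[idx], day[idx]))) {
    if (length(g) > threshold) drop[g] <- TRUE
  }
  events[!drop, , drop = FALSE]
}

# ---- oracle: proactive classification ----------------------------------
# linear scan of every notification for every episode
oracle_proactive <- function(on_times, notif_times, lookback = 60) {
  vapply(as.numeric(on_times), function(on) {
    !any(as.numeric(notif_times) >= on - lookback &
           as.numeric(notif_times) < on)
  }, logical(1))
}

# ---- oracle: single-night detection ------------------------------------
# clip all non-usage episodes to [22:00, 10:00], take the argmax
# (earliest start on ties), restore the winner's pre-clip boundaries
oracle_detect_night <- function(gaps, wake_date, tz = UTC) {
  night <- as.Date(wake_date) - 1
  w0 <- as.numeric(as.POSIXct(paste(night, "22:00:00"), tz = tz))
  w1 <- as.numeric(as.POSIXct(paste(wake_date, "10:00:00"), tz = tz))
  s0 <- as.numeric(as.POSIXct(paste(night, "12:00:00"), tz = tz))
  s1 <- as.numeric(as.POSIXct(paste(wake_date, "12:00:00"), tz = tz))
  st <- as.numeric(gaps$start); en <- as.numeric(gaps$end)
  best <- NULL
  for (i in seq_len(nrow(gaps))) {
    if (st[i] < s0 || en[i] > s1) next       # outside the scan span
    cs <- max(st[i], w0); ce <- min(en[i], w1)
    if (ce <= cs) next                        # no overlap with the window
    d <- ce - cs
    if (is.null(best) || d > best$d || (d == best$d && cs < best$cs))
      best <- list(d = d, cs = cs, ce = ce, onset = st[i], wake = en[i])
  }
  if (is.null(best)) return(NULL)
  # resumption: the pre-clip boundary only when clipping actually moved it
  list(onset = min(best$onset, best$cs) , wake = max(best$wake, best$ce),
       onset_extended = best$onset < w0, wake_extended = best$wake > w1)
}

# random non-usage episodes for one night (seconds relative to the night's
# midnight); returns a nonusage-style frame
random_night_gaps <- function(wake_date = as.Date("2018-03-10"), n = NULL,
                              tz = UTC) {
  if (is.null(n)) n <- sample(0:6, 1)
  midn <- as.numeric(as.POSIXct(paste(wake_date, "00:00:00"), tz = tz))
  # starts anywhere from 11:00 previous day to 13:00 on the wake date
  st <- sort(round(runif(n, -13 * 3600, 13 * 3600))) + midn
  len <- round(runif(n, 300, 12 * 3600))
  en <- st + len
  # enforce disjointness like real gaps between sessions
  if (n > 1) for (i in 2:n) if (st[i] < en[i - 1]) {
    st[i] <- en[i - 1] + sample(60:600, 1)
    en[i] <- st[i] + len[i]
  }
  data.frame(start = as.POSIXct(st, origin = "1970-01-01", tz = tz),
             end = as.POSIXct(en, origin = "1970-01-01", tz = tz),
             start_is_dummy = rep(FALSE, n), end_is_dummy = rep(FALSE, n),
             original_start = as.POSIXct(st, origin = "1970-01-01", tz = tz),
             original_end = as.POSIXct(en, origin = "1970-01-01", tz = tz))
}

# random raw event log over a few days: alternating sessions + notifications
random_event_log <- function(n_days = 2, n_apps = 3, rate_per_day = 30,
                             tz = UTC) {
  t0 <- as.numeric(as.POSIXct("2018-04-01 00:00:00", tz = tz))
  span <- n_days * 86400
  n_sessions <- max(2, rpois(1, 20 * n_days))
  gaps <- round(runif(n_sessions, 60, span / n_sessions))
  durs <- round(runif(n_sessions, 10, 500))
  off <- t0 + cumsum(gaps + durs)
  on <- off - durs
  nt <- unlist(lapply(seq_len(n_apps), function(a)
    round(runif(rpois(1, rate_per_day * n_days), 0, span)) + t0))
  ev(on = as.POSIXct(on, origin = "1970-01-01", tz = tz),
     off = as.POSIXct(off, origin = "1970-01-01", tz = tz),
     notif = as.POSIXct(sort(nt), origin = "1970-01-01", tz = tz),
     app = sample(sprintf("app%02d", seq_len(n_apps)),
                  length(nt), replace = TRUE))
}
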