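# Event-log parsing, flood filtering, episode construction and
# proactive/reactive classification.

EVENT_TYPES <- c("screen_on", "screen_off", "notification")

#' Read a raw event log
#'
#' Parses a per-participant event log from CSV or JSON-lines. Required fields:
#' `timestamp` (ISO-8601 `YYYY-MM-DD[ T]HH:MM:SS` or epoch seconds,
#' auto-detected), `event_type` (`screen_on`, `screen_off`, `notification`)
#' and `app_id` (non-empty for notifications, empty for screen events).
#' Timestamps are interpreted in `cfg$tz` and truncated to whole seconds.
#'
#' Malformed rows (unparseable timestamp, unknown event type, notification
#' without app id) are reported with their line numbers: in strict mode the
#' whole file fails, otherwise the rows are dropped with a warning and
#' recorded in the `"malformed"` attribute of the result.
#'
#' @param path file to read (or a character vector of lines for `format =
#'   "jsonl"` / literal CSV text via `text =` is not supported; pass a path).
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @param cfg a [rhythm_config()].
#' @return a `data.frame` with columns `timestamp` (POSIXct), `event_type`,
#'   `app_id` (NA for screen events), sorted by [sort_events()].
#' @export
read_event_log <- function(path, format = c("auto", "csv", "jsonl"),
                           cfg = rhythm_config()) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(rk_input_error(sprintf("event log '%s' does not exist", path)))
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      data.frame(timestamp = character(), event_type = character(),
                 app_id = character())
    } else {
      recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
      data.frame(
        timestamp = vapply(recs, function(r) as.character(r$timestamp %||% NA),
                           character(1)),
        event_type = vapply(recs, function(r) as.character(r$event_type %||% NA),
                            character(1)),
        app_id = vapply(recs, function(r) as.character(r$app_id %||% ""),
                        character(1))
      )
    }
  }
  parse_event_records(raw, cfg, source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a character data.frame of raw records and build the typed event
# frame. Shared by the CSV and JSONL paths.
parse_event_records <- function(raw, cfg, source = "<input>") {
  need <- c("timestamp", "event_type")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(rk_input_error(sprintf("%s: missing column(s): %s", source,
                                paste(miss, collapse = ", "))))
  if (is.null(raw$app_id)) raw$app_id <- ""
  n <- nrow(raw)
  if (n == 0) {
    warning(sprintf("%s: empty event log", source))
    return(empty_events())
  }
  ts <- parse_timestamps(raw$timestamp, cfg$tz)
  type_ok <- raw$event_type %in% EVENT_TYPES
  app <- trimws(raw$app_id)
  app_ok <- ifelse(raw$event_type == "notification", nzchar(app), TRUE)
  bad <- is.na(ts) | !type_ok | !app_ok
  if (any(bad)) {
    why <- character(sum(bad))
    idx <- which(bad)
    why[is.na(ts[idx])] <- "unparseable timestamp"
    why[!type_ok[idx]] <- sprintf("unknown event_type '%s'",
                                  raw$event_type[idx][!type_ok[idx]])
    w <- type_ok[idx] & !is.na(ts[idx]) & !app_ok[idx]
    why[w] <- "notification without app_id"
    desc <- paste(sprintf("line %d: %s", idx + 1L, why), collapse = "; ")
    if (cfg$strict)
      stop(rk_input_error(sprintf("%s: %d malformed row(s): %s",
                                  source, sum(bad), desc)))
    warning(sprintf("%s: dropped %d malformed row(s): %s",
                    source, sum(bad), desc))
  }
  out <- data.frame(
    timestamp = ts[!bad],
    event_type = raw$event_type[!bad],
    app_id = ifelse(raw$event_type[!bad] == "notification", app[!bad],
                    NA_character_),
    stringsAsFactors = FALSE
  )
  out <- sort_events(out)
  attr(out, "malformed") <- which(bad)
  out
}

empty_events <- function(tz = "UTC") {
  data.frame(timestamp = as.POSIXct(character(), tz = tz),
             event_type = character(), app_id = character())
}

parse_timestamps <- function(x, tz) {
  x <- trimws(x)
  out <- rep(as.POSIXct(NA), length(x))
  epoch <- grepl("^[0-9]+$", x)
  if (any(epoch))
    out[epoch] <- as.POSIXct(as.numeric(x[epoch]), origin = "1970-01-01",
                             tz = tz)
  iso <- !epoch & nzchar(x)
  if (any(iso)) {
    y <- sub("T", " ", x[iso], fixed = TRUE)
    p <- as.POSIXct(strptime(y, "%Y-%m-%d %H:%M:%S", tz = tz))
    short <- is.na(p)
    p[short] <- as.POSIXct(strptime(y[short], "%Y-%m-%d %H:%M", tz = tz))
    out[iso] <- p
  }
  # whole-second resolution throughout
  attr(out, "tzone") <- tz
  as.POSIXct(floor(as.numeric(out)), origin = "1970-01-01", tz = tz)
}

#' Sort events deterministically
#'
#' Stable sort by timestamp; ties are broken `screen_off` < `notification` <
#' `screen_on`, so a zero-gap off/on pair at the same second still yields an
#' empty (discarded) non-usage episode and output order is deterministic.
#'
#' @param events event `data.frame` as from [read_event_log()].
#' @return the sorted `data.frame`.
#' @export
sort_events <- function(events) {
  pri <- match(events$event_type, c("screen_off", "notification", "screen_on"))
  events[order(as.numeric(events$timestamp), pri, method = "radix"), ,
         drop = FALSE]
}

#' Exclude notification floods
#'
#' For every (app, local calendar day) with strictly more than
#' `cfg$flood_threshold` notifications, removes all of that app's
#' notifications on that day. Screen events are never touched. The number of
#' removed rows is attached as attribute `"n_flood_removed"`. The filter is
#' idempotent.
#'
#' @param events sorted event `data.frame`.
#' @param cfg a [rhythm_config()].
#' @return the filtered `data.frame`.
#' @export
filter_notification_floods <- function(events, cfg = rhythm_config()) {
  is_notif <- events$event_type == "notification"
  if (!any(is_notif)) {
    attr(events, "n_flood_removed") <- 0L
    return(events)
  }
  day <- as.Date(format(events$timestamp, "%Y-%m-%d", tz = cfg$tz))
  key <- paste(events$app_id, day, sep = "\r")
  counts <- table(key[is_notif])
  flooded <- names(counts)[counts > cfg$flood_threshold]
  drop <- is_notif & key %in% flooded
  out <- events[!drop, , drop = FALSE]
  attr(out, "n_flood_removed") <- sum(drop)
  out
}

#' Build usage episodes from screen events
#'
#' One episode of use runs from a screen-on to the successive screen-off.
#' Sensor glitches are repaired deterministically: in a run of consecutive
#' screen-ons the episode restarts at the last one; in a run of consecutive
#' screen-offs only the first counts; a leading screen-off and a trailing
#' screen-on have no partner and are discarded. All repairs are counted in
#' attribute `"n_repairs"`.
#'
#' @param events sorted event `data.frame` (notifications are ignored here).
#' @return a `data.frame` with columns `on_time`, `off_time`, `duration`
#'   (seconds) and a placeholder `proactive` column (NA until classified).
#' @export
build_usage_episodes <- function(events) {
  scr <- events[events$event_type %in% c("screen_on", "screen_off"), ,
                drop = FALSE]
  n_rep <- 0L
  if (nrow(scr) == 0) {
    out <- data.frame(on_time = as.POSIXct(character()),
                      off_time = as.POSIXct(character()),
                      duration = numeric(), proactive = logical())
    attr(out, "n_repairs") <- 0L
    return(out)
  }
  r <- rle(scr$event_type)
  # within a run of ons keep the last (restart); within a run of offs keep
  # the first (ignore repeats)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- ifelse(r$values == "screen_on", ends, starts)
  n_rep <- n_rep + (nrow(scr) - length(keep))
  scr <- scr[keep, , drop = FALSE]
  types <- r$values
  if (length(types) && types[1] == "screen_off") {
    scr <- scr[-1, , drop = FALSE]; types <- types[-1]; n_rep <- n_rep + 1L
  }
  if (length(types) && types[length(types)] == "screen_on") {
    scr <- scr[-nrow(scr), , drop = FALSE]; types <- types[-length(types)]
    n_rep <- n_rep + 1L
  }
  stopifnot(nrow(scr) %% 2 == 0)
  if (n_rep > 0)
    message(sprintf("build_usage_episodes: repaired %d malformed screen event(s)",
                    n_rep))
  on_i <- seq(1L, nrow(scr), by = 2L)
  out <- data.frame(on_time = scr$timestamp[on_i],
                    off_time = scr$timestamp[on_i + 1L])
  out$duration <- as.numeric(out$off_time) - as.numeric(out$on_time)
  # zero-length episodes (same-second on/off) carry no usable information
  out <- out[out$duration > 0, , drop = FALSE]
  rownames(out) <- NULL
  out$proactive <- NA
  attr(out, "n_repairs") <- n_rep
  out
}

#' Classify usage episodes as proactive or reactive
#'
#' An episode is proactive iff no (flood-filtered) notification falls in the
#' half-open lookback window `[on_time - reactive_lookback, on_time)`: a
#' notification exactly `reactive_lookback` seconds before the screen-on
#' counts as reactive; one at the same second as the screen-on does not (it
#' did not precede it).
#'
#' @param episodes usage-episode `data.frame` from [build_usage_episodes()].
#' @param notifications event `data.frame` (only notification rows are used),
#'   already flood-filtered and sorted.
#' @param cfg a [rhythm_config()].
#' @return `episodes` with the logical `proactive` column filled in.
#' @export
classify_proactive <- function(episodes, notifications,
                               cfg = rhythm_config()) {
  nt <- sort(as.numeric(
    notifications$timestamp[notifications$event_type == "notification"]))
  on <- as.numeric(episodes$on_time)
  if (!length(nt)) {
    episodes$proactive <- rep(TRUE, length(on))
    return(episodes)
  }
  # whole-second timestamps: counts of t < on minus t < on - lookback
  n_lt_on <- findInterval(on - 0.5, nt)
  n_lt_lb <- findInterval(on - cfg$reactive_lookback - 0.5, nt)
  episodes$proactive <- (n_lt_on - n_lt_lb) == 0L
  episodes
}

#' Build non-usage episodes from proactive usage episodes
#'
#' The gap from each proactive screen-off to the next proactive screen-on is
#' one non-usage episode. Reactive episodes are invisible: they neither start
#' nor end a non-usage episode, so a brief reactive nocturnal check does not
#' split sleep. Fewer than two proactive episodes yield an empty result.
#'
#' @param episodes classified usage episodes; only rows with
#'   `proactive == TRUE` are used.
#' @return a `data.frame` with columns `start`, `end`, `start_is_dummy`,
#'   `end_is_dummy`, `original_start`, `original_end`.
#' @export
build_nonusage_episodes <- function(episodes) {
  pro <- episodes[which(episodes$proactive), , drop = FALSE]
  if (nrow(pro) < 2) return(empty_nonusage())
  start <- pro$off_time[-nrow(pro)]
  end <- pro$on_time[-1]
  keep <- as.numeric(end) > as.numeric(start)
  nonusage_frame(start[keep], end[keep])
}

nonusage_frame <- function(start, end) {
  data.frame(start = start, end = end,
             start_is_dummy = rep(FALSE, length(start)),
             end_is_dummy = rep(FALSE, length(start)),
             original_start = start, original_end = end)
}

empty_nonusage <- function() {
  z <- as.POSIXct(character())
  data.frame(start = z, end = z, start_is_dummy = logical(),
             end_is_dummy = logical(), original_start = z, original_end = z)
}
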