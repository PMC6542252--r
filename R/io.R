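# Readers and writers: event logs, daily summaries, diaries, run
# configuration, provenance. All outputs are plain text and round-trip.

TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

fmt_time <- function(t, tz) format(t, TIME_FMT, tz = tz)

#' Write an event log
#'
#' @param events event `data.frame`.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @param cfg a [rhythm_config()] (time zone for formatting).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, format = c("csv", "jsonl"),
                            cfg = rhythm_config()) {
  format <- match.arg(format)
  out <- data.frame(timestamp = fmt_time(events$timestamp, cfg$tz),
                    event_type = events$event_type,
                    app_id = ifelse(is.na(events$app_id), "", events$app_id))
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(vapply(seq_len(nrow(out)), function(i)
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE),
      character(1)), path)
  }
  invisible(path)
}

#' Write / read the nightly summary CSV
#'
#' One row per participant-night; missing nights keep their row with empty
#' indicator fields. Columns: `participant_id, wake_date, onset, wake,
#' midpoint, tst_seconds, onset_extended, wake_extended, n_candidate_episodes,
#' tie_flag`.
#'
#' @param series a `sleep_series` or list of them.
#' @param path output file.
#' @param cfg a [rhythm_config()].
#' @return `path` invisibly; `read_sleep_summary()` returns a `data.frame`
#'   with POSIXct columns restored.
#' @export
write_sleep_summary <- function(series, path, cfg = rhythm_config()) {
  if (inherits(series, "sleep_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    r <- s$records
    det <- data.frame(participant_id = rep(s$participant_id, nrow(r)),
                      wake_date = format(r$wake_date),
                      onset = fmt_time(r$onset, cfg$tz),
                      wake = fmt_time(r$wake, cfg$tz),
                      midpoint = fmt_time(r$midpoint, cfg$tz),
                      tst_seconds = r$tst,
                      onset_extended = r$onset_extended,
                      wake_extended = r$wake_extended,
                      n_candidate_episodes = r$n_candidates,
                      tie_flag = r$tie)
    if (length(s$missing_nights)) {
      mis <- data.frame(participant_id = s$participant_id,
                        wake_date = format(s$missing_nights),
                        onset = "", wake = "", midpoint = "",
                        tst_seconds = NA_real_, onset_extended = NA,
                        wake_extended = NA, n_candidate_episodes = 0L,
                        tie_flag = NA)
      det <- rbind(det, mis)
    }
    det[order(det$wake_date), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sleep_summary
#' @export
read_sleep_summary <- function(path, cfg = rhythm_config()) {
  d <- utils::read.csv(path, colClasses = "character")
  out <- data.frame(participant_id = d$participant_id,
                    wake_date = as.Date(d$wake_date))
  missing <- !nzchar(d$onset)
  out$onset <- parse_timestamps(ifelse(missing, NA, d$onset), cfg$tz)
  out$wake <- parse_timestamps(ifelse(missing, NA, d$wake), cfg$tz)
  out$midpoint <- parse_timestamps(ifelse(missing, NA, d$midpoint), cfg$tz)
  out$tst <- suppressWarnings(as.numeric(d$tst_seconds))
  out$onset_extended <- as.logical(d$onset_extended)
  out$wake_extended <- as.logical(d$wake_extended)
  out$n_candidates <- as.integer(d$n_candidate_episodes)
  out$tie <- as.logical(d$tie_flag)
  out$missing <- missing
  out
}

#' Read a self-report diary CSV
#'
#' Columns `participant_id, wake_date, onset, wake` (ISO times or epoch
#' seconds).
#'
#' @param path input file.
#' @param cfg a [rhythm_config()].
#' @return a named list of `sleep_series` (one per participant, `source =
#'   "self_report"`).
#' @export
read_self_report <- function(path, cfg = rhythm_config()) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("participant_id", "onset", "wake")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(rk_input_error(sprintf("%s: missing column(s): %s", path,
                                paste(miss, collapse = ", "))))
  lapply(split(d, d$participant_id), function(p)
    self_report_series(p, p$participant_id[1], cfg))
}

write_self_report <- function(self_report, path, cfg = rhythm_config()) {
  out <- data.frame(participant_id = self_report$participant_id,
                    wake_date = format(self_report$wake_date),
                    onset = fmt_time(self_report$onset, cfg$tz),
                    wake = fmt_time(self_report$wake, cfg$tz))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration --------------------------------------------------

RUN_CONFIG_KEYS <- c("reactive_lookback", "flood_threshold", "window_start",
                     "window_end", "scan_start", "scan_end", "tz",
                     "exclude_first_last", "short_sleep_floor",
                     "weekend_basis", "strict", "input", "self_report",
                     "output_dir", "seed", "format")

#' Read / write a run configuration (YAML or JSON)
#'
#' A run configuration holds every [rhythm_config()] field plus `input`
#' (event-log path(s) or directory), `self_report` (diary CSV), `output_dir`,
#' `seed` and `format`. Unknown keys are rejected; a written configuration
#' parses back to an identical object.
#'
#' @param path file (`.yaml`/`.yml` or `.json`).
#' @return a list with elements `config` (a `rhythm_config`) and the run
#'   fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(rk_config_error(sprintf("config '%s' does not exist", path)))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop(rk_config_error(sprintf("unknown config key(s): %s",
                                 paste(unknown, collapse = ", "))))
  cfg_keys <- intersect(names(raw), names(formals(rhythm_config)))
  cfg <- do.call(rhythm_config, raw[cfg_keys])
  run <- raw[setdiff(names(raw), cfg_keys)]
  c(list(config = cfg), run)
}

#' @rdname read_run_config
#' @param run a list as returned by `read_run_config()`.
#' @export
write_run_config <- function(run, path) {
  cfg <- run$config
  flat <- list(reactive_lookback = cfg$reactive_lookback,
               flood_threshold = cfg$flood_threshold,
               window_start = seconds_clock(cfg$window_start),
               window_end = seconds_clock(cfg$window_end),
               scan_start = seconds_clock(cfg$scan_start),
               scan_end = seconds_clock(cfg$scan_end),
               tz = cfg$tz, exclude_first_last = cfg$exclude_first_last,
               short_sleep_floor = cfg$short_sleep_floor,
               weekend_basis = cfg$weekend_basis, strict = cfg$strict)
  flat <- c(flat, run[setdiff(names(run), "config")])
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(flat, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(flat, path)
  invisible(path)
}

# ---- provenance ---------------------------------------------------------

#' Write a provenance block
#'
#' Records the configuration hash, seed and package version of a run as JSON
#' in the output directory, so every output directory is self-describing.
#'
#' @param out_dir output directory.
#' @param run run-configuration list (see [read_run_config()]).
#' @param seed the seed used (or `NA`).
#' @return the provenance file path, invisibly.
#' @export
write_provenance <- function(out_dir, run, seed = NA) {
  tmp <- tempfile()
  write_run_config(run, paste0(tmp, ".yaml"))
  hash <- unname(tools::md5sum(paste0(tmp, ".yaml")))
  unlink(paste0(tmp, ".yaml"))
  prov <- list(config_md5 = hash, seed = seed,
               package = "rhythmkit",
               version = as.character(utils::packageVersion("rhythmkit")))
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
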