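# Synthetic smartphone event-log simulator with known ground-truth sleep.

#' Simulation parameters
#'
#' Defaults emulate a late-chronotype student cohort: 28 participants, 32
#' nights each (so 30 analyzable nights after first/last-day exclusion), mean
#' midpoint of sleep 04:54 with 45 min night-to-night SD, mean total sleep
#' time 6.92 h (SD 60 min, drawn even-second), a 30-min weekend delay of the
#' midpoint (the ground-truth social jetlag), daytime phone sessions as a
#' renewal process (4 sessions/h, mean 300 s, about 5.7 h use/day), reactive
#' nocturnal checks on 20% of nights, 5 apps at 40 notifications/day each
#' plus one flooding app at 600/day, and diary (self-report) boundaries equal
#' to truth plus a fixed bias (onset -4 min, wake +10.4 min) and independent
#' 10-min Gaussian noise per boundary.
#'
#' `n_days` is the number of simulated *nights*; an `n`-night log spans
#' `n + 1` calendar dates.
#'
#' `pre_sleep_gap` / `post_wake_gap` (minutes) separate the last phone use
#' from true sleep onset and true wake from the first use; with the default 0
#' the device boundaries coincide with true sleep and the diary biases carry
#' the whole device-diary discrepancy.
#'
#' @param n_participants,n_days cohort shape (participants, nights each).
#' @param start_date first evening (Date or string).
#' @param midpoint_mean clock time of the mean true midpoint of sleep.
#' @param midpoint_sd night-to-night midpoint SD, minutes.
#' @param tst_mean mean true total sleep time, hours.
#' @param tst_sd total-sleep-time SD, minutes.
#' @param weekend_shift weekend-night midpoint delay, minutes.
#' @param pre_sleep_gap,post_wake_gap minutes, see above.
#' @param daytime_session_rate renewal rate of daytime sessions, per hour.
#' @param session_duration mean session length, seconds.
#' @param nocturnal_check_prob probability per night of one reactive
#'   notification-triggered check during sleep.
#' @param notification_rate_per_app notifications per app per day.
#' @param n_apps number of ordinary apps.
#' @param flood_app_rate notifications/day of the single flooding app (0
#'   disables it).
#' @param self_report_onset_bias,self_report_wake_bias diary bias, minutes
#'   (diary minus truth).
#' @param self_report_noise_sd diary per-boundary noise SD, minutes.
#' @param tz time zone of the simulated log.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(n_participants = 28, n_days = 32,
                       start_date = "2018-03-01",
                       midpoint_mean = "04:54", midpoint_sd = 45,
                       tst_mean = 6.92, tst_sd = 60,
                       weekend_shift = 30,
                       pre_sleep_gap = 0, post_wake_gap = 0,
                       daytime_session_rate = 4, session_duration = 300,
                       nocturnal_check_prob = 0.2,
                       notification_rate_per_app = 40, n_apps = 5,
                       flood_app_rate = 600,
                       self_report_onset_bias = -4,
                       self_report_wake_bias = 10.4,
                       self_report_noise_sd = 10,
                       tz = "UTC", seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            n_days = as.integer(n_days),
            start_date = as.Date(start_date),
            midpoint_mean = clock_seconds(midpoint_mean),
            midpoint_sd = midpoint_sd, tst_mean = tst_mean, tst_sd = tst_sd,
            weekend_shift = weekend_shift,
            pre_sleep_gap = pre_sleep_gap, post_wake_gap = post_wake_gap,
            daytime_session_rate = daytime_session_rate,
            session_duration = session_duration,
            nocturnal_check_prob = nocturnal_check_prob,
            notification_rate_per_app = notification_rate_per_app,
            n_apps = as.integer(n_apps), flood_app_rate = flood_app_rate,
            self_report_onset_bias = self_report_onset_bias,
            self_report_wake_bias = self_report_wake_bias,
            self_report_noise_sd = self_report_noise_sd,
            tz = tz, seed = as.integer(seed))
  rates <- c(p$midpoint_sd, p$tst_sd, p$daytime_session_rate,
             p$session_duration, p$notification_rate_per_app,
             p$flood_app_rate, p$self_report_noise_sd,
             p$pre_sleep_gap, p$post_wake_gap)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop(rk_config_error("sim_params: rates, gaps and SDs must be >= 0"))
  if (p$nocturnal_check_prob < 0 || p$nocturnal_check_prob > 1)
    stop(rk_config_error("sim_params: nocturnal_check_prob must be in [0, 1]"))
  if (p$n_participants < 1 || p$n_days < 1)
    stop(rk_config_error("sim_params: need >= 1 participant and night"))
  if (p$tst_mean * 3600 + 6 * p$tst_sd * 60 >= 22 * 3600)
    stop(rk_config_error("sim_params: total sleep time too close to 24 h"))
  class(p) <- "sim_params"
  p
}

# Bounds on truncated truth draws: sleep stays clear of the surrounding
# daytime and of the nightly scan window.
TST_MIN <- 3 * 3600
TST_MAX <- 13 * 3600

#' Simulate one participant's event log with ground truth
#'
#' Per night, a true sleep interval is drawn (Gaussian midpoint and
#' even-second Gaussian total sleep time, weekend-shifted midpoint on nights
#' waking Saturday/Sunday). Waking hours are filled with proactive phone
#' sessions by a renewal process; the last evening session ends
#' `pre_sleep_gap` minutes before true onset and the first morning session
#' starts `post_wake_gap` minutes after true wake — these two anchor sessions
#' are user-initiated by construction, so notification streams are thinned in
#' the minute before their screen-ons. With probability
#' `nocturnal_check_prob` a night contains one reactive check: a notification
#' 10–50 s before a brief screen-on. Each app emits a homogeneous notification
#' stream; the flooding app (rate > 500/day) is drawn last so that paired-seed
#' runs differing only in flood rate share every other event. The diary is
#' truth plus bias plus noise.
#'
#' The participant's RNG stream is derived from `params$seed` and
#' `participant_index`; draws are ordered truth, diary, nocturnal checks
#' (consumed unconditionally), sessions, notifications, flood, so paired-seed
#' runs differing only in `nocturnal_check_prob` or `flood_app_rate` share
#' all earlier draws.
#'
#' @param params a [sim_params()].
#' @param participant_index 1-based index into the cohort.
#' @return a list: `events` (data frame: `timestamp`, `event_type`,
#'   `app_id`), `truth` (one row per night: `wake_date`, `onset`, `wake`,
#'   `midpoint`, `tst`, `is_weekend_night`, `has_check`), `self_report`
#'   (`wake_date`, `onset`, `wake`).
#' @export
simulate_participant <- function(params, participant_index) {
  p <- params
  set.seed((p$seed + 7919L * as.integer(participant_index)) %% 2147483647L)
  tz <- p$tz
  n <- p$n_days
  wake_dates <- p$start_date + seq_len(n)
  midn <- as.numeric(midnight_of(wake_dates, tz))

  # --- stage 1: truth ----------------------------------------------------
  wknd <- is_weekend_date(wake_dates)
  mid <- midn + round(stats::rnorm(n, p$midpoint_mean +
                                     wknd * p$weekend_shift * 60,
                                   p$midpoint_sd * 60))
  tst <- 2 * round(stats::rnorm(n, p$tst_mean * 3600, p$tst_sd * 60) / 2)
  tst <- pmin(pmax(tst, TST_MIN), TST_MAX)
  # keep each night strictly inside its noon-to-noon scan span: shift rare
  # extreme draws so wake <= 11:30 and onset >= 13:00 the previous day
  mid <- mid - pmax(0, (mid + tst / 2) - (midn + 11.5 * 3600))
  mid <- mid + pmax(0, (midn - 11 * 3600) - (mid - tst / 2))
  onset <- mid - tst / 2
  wake <- mid + tst / 2

  # --- stage 2: diary ----------------------------------------------------
  onset_self <- onset + round(60 * p$self_report_onset_bias +
                                60 * stats::rnorm(n, 0, p$self_report_noise_sd))
  wake_self <- wake + round(60 * p$self_report_wake_bias +
                              60 * stats::rnorm(n, 0, p$self_report_noise_sd))
  bad <- onset_self >= wake_self
  if (any(bad)) { # diary noise cannot invert a night
    onset_self[bad] <- onset[bad]; wake_self[bad] <- wake[bad]
  }

  # --- stage 3: nocturnal checks (draws consumed unconditionally) --------
  u_check <- stats::runif(n)
  frac <- stats::runif(n)
  delay <- round(stats::runif(n, 10, 50))
  check_dur <- round(stats::runif(n, 20, 60))
  has_check <- u_check < p$nocturnal_check_prob

  # --- stage 4: daytime sessions -----------------------------------------
  pre <- p$pre_sleep_gap * 60
  post <- p$post_wake_gap * 60
  day_start <- c(as.numeric(midnight_of(p$start_date, tz)) + 9 * 3600,
                 wake + post)
  day_end <- c(onset - pre, wake[n] + post + 4 * 3600)
  if (any(day_end - day_start < 1800))
    stop(rk_input_error("simulate_participant: nights overlap the surrounding days; lower midpoint_sd/tst_sd or the gaps"))
  anchor_ons <- numeric(0)
  on_t <- off_t <- vector("list", n + 1)
  for (k in seq_len(n + 1)) {
    A <- day_start[k]; B <- day_end[k]
    dA <- min(round(stats::rexp(1, 1 / p$session_duration)) + 10,
              floor((B - A) / 4))
    dB <- min(round(stats::rexp(1, 1 / p$session_duration)) + 10,
              floor((B - A) / 4))
    ons <- A; offs <- A + dA
    t <- A + dA
    gap_rate <- p$daytime_session_rate / 3600
    repeat {
      g <- stats::rexp(1, gap_rate)
      d <- round(stats::rexp(1, 1 / p$session_duration)) + 5
      s_on <- round(t + g)
      s_off <- s_on + d
      if (s_off >= B - dB - 120) break
      ons <- c(ons, s_on); offs <- c(offs, s_off)
      t <- s_off
    }
    ons <- c(ons, B - dB); offs <- c(offs, B)
    on_t[[k]] <- ons; off_t[[k]] <- offs
    anchor_ons <- c(anchor_ons, A, B - dB)
  }
  on_all <- unlist(on_t); off_all <- unlist(off_t)

  # --- check events -------------------------------------------------------
  ck <- which(has_check)
  ck_notif <- onset[ck] + 1800 + floor(frac[ck] * pmax(tst[ck] - 3600, 1))
  ck_on <- ck_notif + delay[ck]
  ck_off <- ck_on + check_dur[ck]

  # --- stage 5: app notifications ----------------------------------------
  span0 <- min(on_all); span1 <- max(off_all)
  span_days <- (span1 - span0) / 86400
  notif_t <- numeric(0); notif_app <- character(0)
  for (a in seq_len(p$n_apps)) {
    m <- stats::rpois(1, p$notification_rate_per_app * span_days)
    notif_t <- c(notif_t, round(stats::runif(m, span0, span1)))
    notif_app <- c(notif_app, rep(sprintf("app%02d", a), m))
  }
  # --- stage 6: flooding app (always last) -------------------------------
  if (p$flood_app_rate > 0) {
    m <- stats::rpois(1, p$flood_app_rate * span_days)
    notif_t <- c(notif_t, round(stats::runif(m, span0, span1)))
    notif_app <- c(notif_app, rep("floodapp", m))
  }
  # thin the minute before anchor screen-ons: anchors are user-initiated
  if (length(notif_t)) {
    drop <- rep(FALSE, length(notif_t))
    for (ao in anchor_ons) drop <- drop | (notif_t >= ao - 60 & notif_t < ao)
    notif_t <- notif_t[!drop]; notif_app <- notif_app[!drop]
  }

  events <- data.frame(
    timestamp = as.POSIXct(
      c(on_all, off_all, ck_on, ck_off, ck_notif, notif_t),
      origin = "1970-01-01", tz = tz),
    event_type = c(rep("screen_on", length(on_all)),
                   rep("screen_off", length(off_all)),
                   rep("screen_on", length(ck_on)),
                   rep("screen_off", length(ck_off)),
                   rep("notification", length(ck_notif) + length(notif_t))),
    app_id = c(rep(NA_character_, 2 * length(on_all) + 2 * length(ck_on)),
               rep("messenger", length(ck_notif)), notif_app),
    stringsAsFactors = FALSE)
  events <- sort_events(events)
  rownames(events) <- NULL

  pos <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = tz)
  truth <- data.frame(wake_date = wake_dates, onset = pos(onset),
                      wake = pos(wake),
                      midpoint = midpoint_of(pos(onset), pos(wake)),
                      tst = tst, is_weekend_night = wknd,
                      has_check = has_check)
  self_report <- data.frame(wake_date = wake_dates, onset = pos(onset_self),
                            wake = pos(wake_self))
  list(events = events, truth = truth, self_report = self_report)
}

#' Simulate a cohort
#'
#' Runs [simulate_participant()] for every participant (each on its own
#' seed-derived RNG stream, so cohort size does not perturb individual logs).
#'
#' @param params a [sim_params()].
#' @return a list: `events` (named list of event data frames, one per
#'   participant), `truth` and `self_report` (row-bound data frames with a
#'   `participant_id` column), `params`.
#' @export
simulate_cohort <- function(params) {
  ids <- sprintf("p%02d", seq_len(params$n_participants))
  sims <- lapply(seq_len(params$n_participants),
                 function(i) simulate_participant(params, i))
  names(sims) <- ids
  bind <- function(field) {
    do.call(rbind, lapply(ids, function(id) {
      d <- sims[[id]][[field]]
      cbind(participant_id = id, d)
    }))
  }
  list(events = lapply(sims, `[[`, "events"),
       truth = bind("truth"), self_report = bind("self_report"),
       params = params)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulation: %d participants x %d nights from %s (seed %d)\n",
              x$n_participants, x$n_days, format(x$start_date), x$seed))
  cat(sprintf("  truth: midpoint %s +- %g min (weekend +%g min), TST %g h +- %g min\n",
              seconds_clock(x$midpoint_mean), x$midpoint_sd, x$weekend_shift,
              x$tst_mean, x$tst_sd))
  cat(sprintf("  behavior: %g sessions/h x %g s, gaps pre/post %g/%g min, nocturnal check p = %g\n",
              x$daytime_session_rate, x$session_duration, x$pre_sleep_gap,
              x$post_wake_gap, x$nocturnal_check_prob))
  cat(sprintf("  notifications: %d apps x %g/day, flood app %g/day\n",
              x$n_apps, x$notification_rate_per_app, x$flood_app_rate))
  cat(sprintf("  diary: bias onset %+g / wake %+g min, noise sd %g min\n",
              x$self_report_onset_bias, x$self_report_wake_bias,
              x$self_report_noise_sd))
  invisible(x)
}
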