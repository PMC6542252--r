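# Event parsing, flood filtering, episode construction, classification.

test_that("event logs parse from CSV and JSONL, sorted, with malformed rows reported", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,event_type,app_id",
               "2018-03-01T10:05:00,screen_off,",
               "2018-03-01T10:00:00,screen_on,",
               "1519898700,notification,mailer"), csv)
  ev <- read_event_log(csv)
  expect_equal(nrow(ev), 3)
  expect_false(is.unsorted(as.numeric(ev$timestamp)))
  expect_equal(ev$event_type[1], "screen_on")
  expect_equal(ev$app_id[ev$event_type == "notification"], "mailer")

  jl <- tempfile(fileext = ".jsonl")
  writeLines(c('{"timestamp":"2018-03-01T10:00:00","event_type":"screen_on","app_id":""}',
               '{"timestamp":"2018-03-01T10:05:00","event_type":"screen_off","app_id":""}'),
             jl)
  expect_equal(nrow(read_event_log(jl)), 2)

  empty <- tempfile(fileext = ".csv")
  writeLines("timestamp,event_type,app_id", empty)
  expect_warning(e0 <- read_event_log(empty), "empty")
  expect_equal(nrow(e0), 0)
})

test_that("strict mode fails on malformed rows naming the line; lenient drops and warns", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,event_type,app_id",
               "2018-03-01T10:00:00,screen_on,",
               "2018-03-01T10:01:00,notify,",
               "not-a-time,screen_off,"), bad)
  expect_error(read_event_log(bad, cfg = rhythm_config(strict = TRUE)),
               "line 3.*notify", class = "rk_input_error")
  expect_warning(ok <- read_event_log(bad), "2 malformed")
  expect_equal(nrow(ok), 1)
  # notification without an app id is malformed too
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,event_type,app_id",
               "2018-03-01T10:00:00,notification,"), bad2)
  expect_error(read_event_log(bad2, cfg = rhythm_config(strict = TRUE)),
               "without app_id", class = "rk_input_error")
})

test_that("timestamp ties sort screen_off < notification < screen_on", {
  e <- ev(on = "2018-03-01 10:00:00", off = "2018-03-01 10:00:00",
          notif = "2018-03-01 10:00:00")
  expect_equal(e$event_type,
               c("screen_off", "notification", "screen_on"))
})

test_that("flood filter drops whole (app, day) groups strictly above threshold", {
  day <- as.POSIXct("2018-03-05 00:00:00", tz = UTC)
  mk <- function(app, n, d = day) data.frame(
    timestamp = d + sort(round(seq(3600, 80000, length.out = n))),
    event_type = "notification", app_id = app)
  scr <- data.frame(timestamp = day + c(100, 200),
                    event_type = c("screen_on", "screen_off"),
                    app_id = NA_character_)
  events <- sort_events(rbind(mk("A", 501), mk("B", 10), scr))
  out <- filter_notification_floods(events)
  expect_equal(sum(out$app_id == "A", na.rm = TRUE), 0)   # 501 > 500: all gone
  expect_equal(sum(out$app_id == "B", na.rm = TRUE), 10)
  expect_equal(sum(out$event_type != "notification"), 2)  # screen events untouched
  expect_equal(attr(out, "n_flood_removed"), 501L)

  # exactly 500 on the day is kept: the rule is "more than 500"
  at_thresh <- sort_events(rbind(mk("A", 500), scr))
  expect_equal(sum(filter_notification_floods(at_thresh)$app_id == "A",
                   na.rm = TRUE), 500)
})

test_that("flood filter equals the per-(app, day) counting oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:20) {
    t0 <- as.POSIXct("2018-03-01 00:00:00", tz = UTC)
    n <- sample(200:1500, 1)
    events <- data.frame(
      timestamp = t0 + round(runif(n, 0, 7 * 86400)),
      event_type = "notification",
      app_id = sample(paste0("app", 1:5), n, replace = TRUE))
    events <- sort_events(events)
    cfg <- rhythm_config(flood_threshold = sample(10:60, 1))
    got <- filter_notification_floods(events, cfg)
    want <- oracle_flood_filter(events, cfg$flood_threshold)
    expect_equal(got$timestamp, want$timestamp)
    expect_equal(got$app_id, want$app_id)
    twice <- filter_notification_floods(got, cfg)
    expect_equal(twice$timestamp, got$timestamp)
  }
})

test_that("usage episodes pair each screen-on with the next screen-off", {
  e <- ev(on = c("2018-03-01 10:00:00", "2018-03-01 11:00:00"),
          off = c("2018-03-01 10:05:00", "2018-03-01 11:01:00"))
  ep <- build_usage_episodes(e)
  expect_equal(ep$duration, c(300, 60))
  expect_true(all(ep$off_time[-nrow(ep)] <= ep$on_time[-1]))
})

test_that("malformed screen sequences are repaired deterministically", {
  # consecutive screen-ons: restart at the second
  e <- ev(on = c("2018-03-01 10:00:00", "2018-03-01 10:02:00"),
          off = "2018-03-01 10:05:00")
  expect_message(ep <- build_usage_episodes(e), "repaired")
  expect_equal(as.numeric(ep$duration), 180)
  expect_equal(attr(ep, "n_repairs"), 1L)
  # consecutive screen-offs: ignore the second
  e2 <- ev(on = "2018-03-01 10:00:00",
           off = c("2018-03-01 10:05:00", "2018-03-01 10:09:00"))
  expect_message(ep2 <- build_usage_episodes(e2), "repaired")
  expect_equal(as.numeric(ep2$duration), 300)
  # trailing screen-on has no partner and is discarded
  e3 <- ev(on = c("2018-03-01 10:00:00", "2018-03-01 12:00:00"),
           off = "2018-03-01 10:05:00")
  expect_message(ep3 <- build_usage_episodes(e3), "repaired")
  expect_equal(nrow(ep3), 1)
})

test_that("proactive classification follows the half-open one-minute lookback", {
  cfg <- rhythm_config()
  mk <- function(notif) classify_proactive(
    build_usage_episodes(ev(on = "2018-03-01 10:00:00",
                            off = "2018-03-01 10:05:00")),
    ev(on = "2018-03-01 09:00:00", off = "2018-03-01 09:00:10",
       notif = notif), cfg)$proactive
  expect_false(mk("2018-03-01 09:59:30"))  # 30 s before: reactive
  expect_true(mk("2018-03-01 08:00:00"))   # nothing within the hour before
  expect_false(mk("2018-03-01 09:59:00"))  # exactly 60 s before: included
  expect_true(mk("2018-03-01 10:00:00"))   # same second as screen-on: excluded
})

test_that("classification equals a linear-scan oracle on random logs", {
  set.seed(7)
  for (rep in 1:50) {
    log <- random_event_log()
    eps <- classify_proactive(build_usage_episodes(log), log)
    want <- oracle_proactive(eps$on_time,
                             log$timestamp[log$event_type == "notification"])
    expect_equal(eps$proactive, want)
  }
})

test_that("removing notifications can only flip episodes reactive -> proactive", {
  set.seed(8)
  for (rep in 1:20) {
    log <- random_event_log(n_apps = 4, rate_per_day = 120)
    eps <- build_usage_episodes(log)
    full <- classify_proactive(eps, log)$proactive
    drop_app <- sample(unique(stats::na.omit(log$app_id)), 1)
    thinned <- log[!(log$event_type == "notification" &
                       log$app_id == drop_app), ]
    less <- classify_proactive(eps, thinned)$proactive
    expect_true(all(less >= full))  # proactive episodes never become reactive
  }
})

test_that("non-usage episodes are the gaps between consecutive proactive episodes", {
  eps <- data.frame(
    on_time = pt(c("2018-03-01 22:30:00", "2018-03-02 07:00:00")),
    off_time = pt(c("2018-03-01 23:00:00", "2018-03-02 07:10:00")),
    proactive = TRUE)
  g <- build_nonusage_episodes(eps)
  expect_equal(nrow(g), 1)
  expect_equal(g$start, pt("2018-03-01 23:00:00"))
  expect_equal(g$end, pt("2018-03-02 07:00:00"))
  expect_false(g$start_is_dummy || g$end_is_dummy)

  # a reactive nocturnal check does not split the gap
  eps_rx <- rbind(eps, data.frame(
    on_time = pt("2018-03-02 03:00:00"),
    off_time = pt("2018-03-02 03:05:00"), proactive = FALSE))
  g2 <- build_nonusage_episodes(eps_rx[order(eps_rx$on_time), ])
  expect_equal(nrow(g2), 1)
  expect_equal(g2$end, pt("2018-03-02 07:00:00"))

  # fewer than two proactive episodes: nothing to bound a gap
  expect_equal(nrow(build_nonusage_episodes(eps[1, ])), 0)
})

test_that("gaps equal the zip of consecutive proactive boundaries (property)", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    on <- sort(as.numeric(pt("2018-03-01 08:00:00")) +
                 cumsum(sample(600:3600, n)))
    off <- on + sample(30:500, n)
    eps <- data.frame(
      on_time = as.POSIXct(on, origin = "1970-01-01", tz = UTC),
      off_time = as.POSIXct(off, origin = "1970-01-01", tz = UTC),
      proactive = runif(n) < 0.7)
    g <- build_nonusage_episodes(eps)
    pro <- eps[eps$proactive, ]
    if (nrow(pro) >= 2) {
      expect_equal(as.numeric(g$start), as.numeric(pro$off_time[-nrow(pro)]))
      expect_equal(as.numeric(g$end), as.numeric(pro$on_time[-1]))
    } else expect_equal(nrow(g), 0)
  }
})

test_that("usage and non-usage episodes tile the span of a well-formed log", {
  set.seed(10)
  log <- random_event_log(n_days = 1, rate_per_day = 0)
  eps <- build_usage_episodes(log)
  eps$proactive <- TRUE
  gaps <- build_nonusage_episodes(eps)
  covered <- sum(eps$duration) + sum(as.numeric(gaps$end) -
                                       as.numeric(gaps$start))
  span <- as.numeric(max(eps$off_time)) - as.numeric(min(eps$on_time))
  expect_equal(covered, span)
})
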