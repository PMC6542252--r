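# Dummy-boundary labelling, maximal non-usage detection, resumption,
# series construction.

gap <- function(start, end) nonusage_df(pt(start), pt(end))
nonusage_df <- function(start, end) data.frame(
  start = start, end = end, start_is_dummy = FALSE, end_is_dummy = FALSE,
  original_start = start, original_end = end)

test_that("dummy boundaries replace starts before 22:00 and ends after 10:00", {
  night <- as.Date("2018-03-01")
  lab <- label_dummy_boundaries(gap("2018-03-01 21:30:00", "2018-03-02 08:00:00"),
                                night)
  expect_equal(lab$start, pt("2018-03-01 22:00:00"))
  expect_true(lab$start_is_dummy)
  expect_equal(lab$original_start, pt("2018-03-01 21:30:00"))
  expect_false(lab$end_is_dummy)

  unchanged <- label_dummy_boundaries(
    gap("2018-03-01 23:00:00", "2018-03-02 07:00:00"), night)
  expect_equal(unchanged$start, pt("2018-03-01 23:00:00"))
  expect_false(any(unchanged$start_is_dummy, unchanged$end_is_dummy))

  # entirely outside the window: dropped
  outside <- label_dummy_boundaries(
    gap("2018-03-01 20:00:00", "2018-03-01 21:00:00"), night)
  expect_equal(nrow(outside), 0)

  late <- label_dummy_boundaries(
    gap("2018-03-02 02:00:00", "2018-03-02 11:30:00"), night)
  expect_true(late$end_is_dummy)
  expect_equal(late$end, pt("2018-03-02 10:00:00"))
  expect_equal(late$original_end, pt("2018-03-02 11:30:00"))
})

test_that("midpoint is the half-way clock time, whole-second rounded", {
  expect_equal(midpoint_of(pt("2018-03-02 01:00:00"), pt("2018-03-02 09:00:00")),
               pt("2018-03-02 05:00:00"))
  # crosses midnight; equals the epoch-seconds mean
  o <- pt("2018-03-01 23:00:00"); w <- pt("2018-03-02 06:00:00")
  expect_equal(as.numeric(midpoint_of(o, w)),
               floor(mean(c(as.numeric(o), as.numeric(w))) + 0.5))
  expect_equal(format(midpoint_of(o, w), "%H:%M:%S"), "02:30:00")
  # two-second night rounds up to onset + 1
  o2 <- pt("2018-03-02 03:00:00")
  expect_equal(midpoint_of(o2, o2 + 2), o2 + 1)
  expect_error(midpoint_of(o2, o2), class = "rk_input_error")
})

test_that("detect_sleep picks the maximal episode and resumes dummy boundaries", {
  wd <- as.Date("2018-03-02")
  # unique maximum, no dummies
  g1 <- rbind(gap("2018-03-01 23:00:00", "2018-03-02 07:00:00"),
              gap("2018-03-02 01:00:00", "2018-03-02 01:30:00"))
  # (overlapping gaps cannot arise from one log; harmless for the selector)
  r1 <- detect_sleep(g1, wd)
  expect_equal(r1$onset, pt("2018-03-01 23:00:00"))
  expect_equal(r1$wake, pt("2018-03-02 07:00:00"))
  expect_equal(r1$tst, 28800)
  expect_equal(format(r1$midpoint, "%H:%M:%S"), "03:00:00")
  expect_false(r1$onset_extended || r1$wake_extended)

  # dummy-started winner: clipped 36000 s beats 4800 s, onset resumes to 21:30
  g2 <- rbind(gap("2018-03-01 21:30:00", "2018-03-02 08:00:00"),
              gap("2018-03-01 22:30:00", "2018-03-01 23:50:00"))
  r2 <- detect_sleep(g2, wd)
  expect_equal(r2$onset, pt("2018-03-01 21:30:00"))
  expect_true(r2$onset_extended)
  expect_equal(r2$tst, 37800)

  # nothing overlapping the window: missing night
  expect_null(detect_sleep(gap("2018-03-01 13:00:00", "2018-03-01 14:00:00"), wd))
})

test_that("equal-duration maxima resolve to the earliest start, flagged", {
  wd <- as.Date("2018-03-02")
  g <- rbind(gap("2018-03-01 23:00:00", "2018-03-02 02:00:00"),
             gap("2018-03-02 04:00:00", "2018-03-02 07:00:00"))
  expect_message(r <- detect_sleep(g, wd), "equal-duration")
  expect_equal(r$onset, pt("2018-03-01 23:00:00"))
  expect_true(r$tie)
})

test_that("detect_sleep equals the clip-argmax-unclip oracle on random nights", {
  set.seed(123)
  wd <- as.Date("2018-03-10")
  n_checked <- 0
  for (rep in 1:300) {
    g <- random_night_gaps(wd)
    got <- detect_sleep(g, wd)
    want <- oracle_detect_night(g, wd)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_checked <- n_checked + 1
      expect_equal(as.numeric(got$onset), want$onset)
      expect_equal(as.numeric(got$wake), want$wake)
      expect_equal(got$onset_extended, want$onset_extended)
      expect_equal(got$wake_extended, want$wake_extended)
    }
  }
  expect_gt(n_checked, 100)
})

test_that("resumption only widens: reported TST >= clipped TST; winner is maximal", {
  set.seed(321)
  wd <- as.Date("2018-03-10")
  w0 <- as.numeric(pt("2018-03-09 22:00:00"))
  w1 <- as.numeric(pt("2018-03-10 10:00:00"))
  for (rep in 1:100) {
    g <- random_night_gaps(wd)
    r <- detect_sleep(g, wd)
    if (is.null(r)) next
    clip <- function(s, e) pmax(0, pmin(e, w1) - pmax(s, w0))
    clipped_winner <- clip(as.numeric(r$onset), as.numeric(r$wake))
    expect_gte(r$tst, clipped_winner)
    # window maximality over every candidate episode that night
    cand <- g[as.numeric(g$start) >= w0 - 10 * 3600 &
                as.numeric(g$end) <= w1 + 2 * 3600, ]
    expect_gte(clipped_winner + 1e-9,
               max(clip(as.numeric(cand$start), as.numeric(cand$end))))
  }
})

test_that("series detection equals night-by-night single calls", {
  sim <- simulate_participant(sim_params(n_days = 10, seed = 5), 1)
  fit <- detect_sleep_series(sim$events, "p01")
  cfg <- rhythm_config()
  gaps <- build_nonusage_episodes(classify_proactive(
    build_usage_episodes(sort_events(filter_notification_floods(
      sort_events(sim$events), cfg))),
    filter_notification_floods(sort_events(sim$events), cfg), cfg))
  for (i in seq_len(nrow(fit$records))) {
    single <- detect_sleep(gaps, fit$records$wake_date[i], cfg)
    expect_equal(single$onset, fit$records$onset[i])
    expect_equal(single$wake, fit$records$wake[i])
  }
})

test_that("first/last-day exclusion yields n - 2 analyzable nights", {
  sim <- simulate_participant(sim_params(n_days = 32, seed = 2), 1)
  fit <- detect_sleep_series(sim$events, "p01")
  expect_equal(nrow(fit$records) + length(fit$missing_nights), 30)
  off <- detect_sleep_series(sim$events, "p01",
                             rhythm_config(exclude_first_last = FALSE))
  expect_equal(nrow(off$records) + length(off$missing_nights), 32)
  # tiny log: 3 nights leave a single analyzable one
  sim3 <- simulate_participant(sim_params(n_days = 3, seed = 2), 1)
  fit3 <- detect_sleep_series(sim3$events, "p01")
  expect_equal(nrow(fit3$records) + length(fit3$missing_nights), 1)
})

test_that("a phone-silent day becomes an explicit missing night", {
  sim <- simulate_participant(
    sim_params(n_days = 6, seed = 13, nocturnal_check_prob = 0,
               notification_rate_per_app = 0, flood_app_rate = 0), 1)
  ev <- sim$events
  # phone untouched from the previous evening through the following noon
  d <- sort(unique(as.Date(format(ev$timestamp, "%Y-%m-%d"))))[3]
  q0 <- pt(paste(d - 1, "20:00:00")); q1 <- pt(paste(d + 1, "12:00:00"))
  ev <- ev[ev$timestamp < q0 | ev$timestamp >= q1, ]
  fit <- detect_sleep_series(ev, "p01")
  expect_true(d %in% fit$missing_nights)
  expect_true((d + 1) %in% fit$missing_nights)
  expect_warning(empty <- detect_sleep_series(ev[0, ], "p01"), "empty")
  expect_equal(nrow(empty$records), 0)
})

test_that("sleep_series methods print, summarize and convert", {
  sim <- simulate_participant(sim_params(n_days = 10, seed = 6), 1)
  fit <- detect_sleep_series(sim$events, "p01")
  expect_output(print(fit), "Sleep series for 'p01'")
  s <- summary(fit)
  expect_output(print(s), "social jetlag")
  df <- as.data.frame(fit)
  expect_true(all(c("participant_id", "wake_date", "onset", "wake",
                    "midpoint", "tst") %in% names(df)))
  expect_true(all(diff(as.numeric(df$wake_date)) > 0))
  # invariants of every record
  expect_true(all(df$onset < df$wake))
  expect_equal(df$tst, as.numeric(df$wake) - as.numeric(df$onset))
  pdf(NULL); plot(fit); dev.off()
})

test_that("self-report series derive midpoint and tst and reject bad diaries", {
  d <- data.frame(onset = c("2018-03-01T23:30:00", "2018-03-03T00:10:00"),
                  wake = c("2018-03-02T07:30:00", "2018-03-03T08:00:00"))
  s <- self_report_series(d, "p01")
  expect_s3_class(s, "sleep_series")
  expect_equal(s$source, "self_report")
  expect_equal(s$records$tst, c(28800, 28200))
  expect_equal(format(s$records$midpoint[1], "%H:%M:%S"), "03:30:00")
  bad <- data.frame(onset = "2018-03-02T09:00:00", wake = "2018-03-02T08:00:00")
  expect_error(self_report_series(bad), class = "rk_input_error")
})
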