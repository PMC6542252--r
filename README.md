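# rhythmkit

Sleep and circadian-rhythm inference from passively collected smartphone
screen events.

## The problem

Sleep diaries are burdensome and coarse (typically 1-hour resolution);
actigraphy and polysomnography are expensive. A smartphone, however, records
its own screen-on/screen-off transitions and incoming notifications at
1-second resolution, and for most people the longest stretch of *not
touching the phone* at night is sleep. `rhythmkit` turns raw event streams
(`screen_on`, `screen_off`, `notification` + app id) into nightly sleep
records — onset, wake time, midpoint of sleep, total sleep time (TST) — and
month-scale circadian summaries, and validates them against self-reported
sleep. It is aimed at digital-phenotyping and chronobiology studies that
collect passive mobile-sensing logs.

## The algorithm

1. **Episodes.** Use runs from a screen-on to the successive screen-off;
   the interval from a screen-off to the next screen-on is a non-usage
   episode.
2. **Proactive vs reactive use.** An episode with no notification in the
   minute before its screen-on (half-open window `[on − 60 s, on)`) is
   *proactive* (user-initiated); otherwise *reactive*. Only proactive
   episodes can delimit sleep, so answering a 3 a.m. message does not split
   the night. To keep notification-heavy apps from relabelling everything
   reactive, any app issuing more than 500 notifications in a calendar day
   has all of that day's notifications excluded first.
3. **Nightly detection.** Within the night window 22:00 → 10:00, non-usage
   episodes crossing a boundary get *dummy* boundaries (screen-off at
   22:00, screen-on at 10:00). The maximal remaining episode is sleep; if
   the winner carries a dummy boundary, the original screen-off/screen-on
   is resumed as onset/wake, so late bedtimes and long lie-ins are traced
   beyond the window (bounded by a noon-to-noon scan span).
4. **Validation metrics.** Night-level agreement between a device interval
   and a diary interval is the overlap ratio

   `Overlap ratio = |A ∩ B| / ((|A| + |B|) / 2) × 100%`.

   Cohort statistics: paired t tests of onset/wake/midpoint/TST on the
   elapsed-seconds-since-midnight scale, Pearson correlation of midpoints
   (overall and per study day), social jetlag (|mean weekend-night midpoint −
   mean weeknight midpoint| in minutes), and a sleep-efficiency proxy
   TST_device / TST_diary.

A synthetic event-log generator with known ground truth (true sleep,
bedtime/lingering gaps, reactive nocturnal checks, per-app notification
streams including a flooding app, biased noisy diaries) makes the whole
pipeline testable end to end.

## Worked example

```r
library(rhythmkit)

p   <- sim_params(n_participants = 4, n_days = 12, seed = 42)
sim <- simulate_cohort(p)

fit <- detect_sleep_series(sim$events[["p01"]], "p01")
fit
#> Sleep series for 'p01' (app): 10 night(s), 0 missing
#>   nights 2018-03-03 .. 2018-03-12
#>   mean onset 01:36:32, wake 08:09:22, midpoint 04:52:57, TST 6.55 h
```

Twelve simulated nights leave 10 records because the incomplete first and
last calendar days are excluded. Comparing the whole cohort's detected
records with its simulated diaries:

```r
fits  <- lapply(names(sim$events), \(id) detect_sleep_series(sim$events[[id]], id))
selfs <- lapply(split(sim$self_report, sim$self_report$participant_id),
                \(d) self_report_series(d, d$participant_id[1]))
sleep_agreement(fits, selfs)
#> Device vs diary sleep agreement: 40 night pairs (8 unmatched)
#>   mean overlap ratio: 97.5%
#>   paired differences (device - diary, participant level, n = 4):
#>     onset      +180.8 s   t = 1.43, p = 0.249
#>     wake       -709.3 s   t = -7.76, p = 0.00446
#>     midpoint   -264.4 s   t = -3.13, p = 0.0521
#>     tst        -890.2 s   t = -6.25, p = 0.00828
#>   midpoint correlation: overall r = 0.988 (N = 40); daily r in [-0.30, 1.00] over 10 day(s)
#>   social jetlag: device 58.0 min vs diary 59.0 min (paired p = 0.724)
#>   overlap weeknight 97.8% vs weekend 97.0% (paired p = 0.0977)
#>   mean sleep efficiency (TST_app/TST_self): 0.964 (4 pair(s) > 1)
```

The generator's diaries are biased −4 min at onset and +10.4 min at wake,
so the device records look ~3 min later at onset, ~12 min earlier at wake
and ~15 min shorter in TST — the signs the paired differences recover. The
overlap ratio and midpoint correlation quantify night-level and
circadian-level agreement; social jetlag compares weekend against weekday
sleep timing in both sources.

The same workflow is scriptable from a shell via
`inst/cli/rhythmkit.R detect | validate | simulate | report`
(`--show-config` prints every default; exit codes: 0 ok, 2 input error,
3 config error).

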