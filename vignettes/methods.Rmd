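---
title: "Inferring sleep and circadian rhythm from smartphone screen events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sleep and circadian rhythm from smartphone screen events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmkit)
```

## The model

`rhythmkit` treats a phone as a crude but ubiquitous sleep sensor. The raw
data are one participant's timestamped events at 1-second resolution:
`screen_on`, `screen_off`, and `notification` (with an app identifier).
The behavioural model has three layers.

**Usage episodes.** A use episode runs from a screen-on to the successive
screen-off; the complementary interval from a screen-off to the next
screen-on is a non-usage episode. All internal arithmetic is in whole
seconds, the native resolution of the stream.

**Proactive vs reactive use.** Sleep should only be bounded by phone use
the *user* initiated. An episode is *reactive* when a notification arrived
in the minute before its screen-on, and *proactive* otherwise. The lookback
is the half-open interval `[on − 60 s, on)`: a notification exactly 60 s
before the screen-on still counts as preceding it, one at the same second
does not. Reactive episodes are invisible to sleep detection — a brief
answer to a nocturnal message neither starts nor ends a non-usage episode.
Because chatty apps could mislabel every episode reactive, the
notification-flood rule runs first: for every (app, calendar day) with
strictly more than 500 notifications, all of that app's notifications that
day are excluded. The filter is applied before classification, matching its
purpose (keeping floods from confounding proactive use), and excluded
notifications are fully invisible downstream.

**Nightly maximal non-usage.** For the night waking on date $W$, candidate
non-usage episodes are those contained in the scan span from noon on
$W-1$ to noon on $W$. Within the night window 22:00 → 10:00, episodes
crossing a boundary receive *dummy* boundaries (a screen-off at 22:00
and/or a screen-on at 10:00; the originals are preserved), and episodes
wholly outside the window are dropped. The longest remaining episode is the
night's sleep. If the winner starts or ends at a dummy boundary, the
original screen-off/screen-on is resumed as onset/wake, so a 21:30 bedtime
or an 11:30 lie-in is reported correctly while the *selection* still
happens inside the standard window. Midpoint of sleep is the half-way clock
time (rounded half-up to the second); TST is wake minus onset.

Requiring *containment* in the noon-to-noon span (not mere intersection)
does two jobs at once: it bounds how far resumption can reach (a boundless
rule would absorb daytime naps into the night), and it makes a phone-silent
day produce an explicit missing night rather than a fabricated noon-clamped
record. Missing nights are never interpolated; downstream statistics drop
them pairwise.

Ties in maximal duration are resolved to the earliest-starting episode and
flagged. Records shorter than a 3-hour floor are flagged as suspicious
(naps and shift-work sleep are out of scope by design). Nights whose first
or last calendar day is incomplete — the log's edges — are excluded by
default (`exclude_first_last`).

## Agreement and circadian statistics

All indicator arithmetic uses *elapsed seconds since midnight of the wake
date*, so an onset before midnight is negative and each night is internally
continuous; this is also the scale on which cohort means are reported.

* **Overlap ratio** between a device interval $A$ and diary interval $B$:
  $|A \cap B| \,/\, \big((|A|+|B|)/2\big) \times 100\%$ — symmetric,
  bounded in $[0, 100]$, and 100 exactly when the intervals coincide.
* **Paired indicator differences** (onset, wake, midpoint, TST): the unit
  of analysis defaults to the participant — per-participant means over
  nights are formed first and a two-tailed paired t test compares those
  means — matching the usual cohort design; night-level pooling is
  available (`unit = "night"`). Zero-variance differences yield an
  explicitly flagged undefined t rather than ±∞.
* **Midpoint correlation**: Pearson r of device vs diary midpoints, pooled
  over all pairs and/or one coefficient per study day across participants;
  undefined below 3 pairs or under zero variance, with the reason reported.
* **Social jetlag**: per participant, |mean weekend-night midpoint − mean
  weeknight midpoint| in minutes. A weekend night is one whose wake
  morning is Saturday or Sunday (Fri→Sat and Sat→Sun sleep); because the
  convention is not universal, `weekend_basis = "onset_date"` switches to
  classifying by the evening's date. The absolute value makes the measure
  invariant to relabelling the classes. Device and diary jetlag are
  compared by a paired t test across participants.
* **Sleep efficiency proxy**: treating the diary interval as time in bed,
  TST_device / TST_diary, unclamped; ratios above 1 are counted and
  surfaced.

No multiplicity correction is applied across the battery; the report is
descriptive and each test is interpreted at face value.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `reactive_lookback` | 60 s | notification lookback defining reactive use |
| `flood_threshold` | 500 /app/day | strict exclusion threshold |
| `window_start`, `window_end` | 22:00, 10:00 | nightly selection window |
| `scan_start`, `scan_end` | 12:00, 12:00 | containment span and resumption bound |
| `short_sleep_floor` | 3 h | flag threshold for suspect records |
| `tz` | UTC | participant-level zone; all parsing uses it |

Times are interpreted in a single participant-level zone; nights whose
onset and wake carry different UTC offsets (a DST transition) are flagged
in the output rather than silently adjusted.

## The synthetic generator

`sim_params()` / `simulate_cohort()` generate event logs with known ground
truth. Defaults describe a late-chronotype student cohort over a month:
28 participants × 32 nights (30 analyzable after edge exclusion); true
midpoint of sleep N(04:54, 45 min) with a +30 min weekend shift; true TST
N(6.92 h, 60 min), drawn even-second so the midpoint is exact; daytime
sessions as a renewal process (exponential gaps at 4 sessions/h,
exponential durations of mean 300 s ⇒ ≈5.7 h screen time/day); five apps
at 40 notifications/day plus one flooding app at 600/day; a reactive
nocturnal check (notification 10–50 s before a brief screen-on) on 20% of
nights; and diaries equal to truth plus fixed biases (−4 min onset,
+10.4 min wake) plus independent N(0, 10 min) noise per boundary. Rare
extreme draws are truncated/shifted so each night stays strictly inside
its noon-to-noon span (TST clamped to 3–13 h, wake no later than 11:30).

Two construction choices matter for interpretation:

* The last pre-sleep session ends exactly `pre_sleep_gap` before true
  onset and the first post-wake session starts `post_wake_gap` after true
  wake. These **anchor sessions are user-initiated by construction**:
  notification streams are thinned in the minute before their screen-ons.
  Without this, a random notification could relabel a boundary session
  reactive and the generator's own ground truth would be unrecoverable
  even by a perfect detector. With the default gaps of 0, the device
  boundaries coincide with true sleep and the diary biases carry the whole
  device–diary discrepancy, which is what the bias-recovery tests exploit.
* Per-participant RNG streams are derived from the seed and the
  participant index, and draws are ordered truth → diary → nocturnal
  checks (consumed unconditionally) → sessions → notifications → flooding
  app. Paired-seed runs that differ only in the check probability or the
  flood rate therefore share every other event — the basis of the
  "reactive use is invisible" and "the flooding app is invisible" tests.

What the generator does **not** emulate: real within-person autocorrelation
of sleep timing, naps and interrupted sleep, shift work, app-specific
notification bursts, phone-off days, or DST transitions (a single zone by
default). Passing tests therefore demonstrate algorithmic correctness under
the stated behavioural model, not field validity on arbitrary populations.

## Numerical and design choices

* Deterministic event ordering: stable sort by timestamp, ties ordered
  screen-off < notification < screen-on, so a zero-gap off/on pair yields
  an empty, discarded non-usage episode.
* Glitch repair: a run of screen-ons restarts the episode at the last one;
  a run of screen-offs keeps the first; unpaired leading screen-offs and
  trailing screen-ons are discarded. Repairs are counted and logged; with
  `strict = TRUE` malformed *rows* fail the whole file with line numbers.
* Flood counting uses the local calendar day of each notification, the
  simplest reading of a per-day rule.
* Records are keyed by the wake date (the morning), the natural index for
  "last night's sleep".
* Problem sizes in the test suite — ≥1000 random nights against a
  brute-force clip–argmax–unclip oracle, a full 28 × 30 cohort for exact
  noise-free recovery and for bias/jetlag/attenuation recovery — keep the
  whole suite under a minute while exercising every code path at the
  cohort scale the defaults describe.

## Limitations

The detector assumes one consolidated nocturnal sleep bounded by proactive
phone use: it cannot see sleep interruptions that involve proactive use,
daytime sleep of shift workers, or nights when the phone is simply not
used (reported as missing). The sleep-efficiency proxy inherits the
diary's validity as a time-in-bed measure. The elapsed-since-midnight
scale assumes onset falls between the previous noon and the wake-date noon
— guaranteed by the scan-window containment, but a convention to keep in
mind when feeding external records into the metrics directly.
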