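# Agreement and circadian statistics: overlap ratio, paired indicator
# differences, midpoint correlations, social jetlag, sleep efficiency.

#' Interval overlap ratio
#'
#' Night-level agreement between two sleep intervals:
#' `overlap / ((len_a + len_b) / 2) * 100`, the length of the intersection
#' divided by the mean of the two interval lengths, as a percentage. Zero for
#' disjoint intervals; 100 iff the intervals coincide. Vectorized.
#'
#' @param onset_a,wake_a,onset_b,wake_b POSIXct (or numeric seconds); each
#'   onset strictly before its wake.
#' @return numeric percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' overlap_ratio(as.POSIXct("2018-03-02 23:36:00", tz = "UTC"),
#'               as.POSIXct("2018-03-03 06:49:00", tz = "UTC"),
#'               as.POSIXct("2018-03-02 23:00:00", tz = "UTC"),
#'               as.POSIXct("2018-03-03 06:00:00", tz = "UTC"))
overlap_ratio <- function(onset_a, wake_a, onset_b, wake_b) {
  oa <- as.numeric(onset_a); wa <- as.numeric(wake_a)
  ob <- as.numeric(onset_b); wb <- as.numeric(wake_b)
  if (any(oa >= wa) || any(ob >= wb))
    stop(rk_input_error("overlap_ratio: degenerate interval (onset >= wake)"))
  ov <- pmax(0, pmin(wa, wb) - pmax(oa, ob))
  100 * ov / (((wa - oa) + (wb - ob)) / 2)
}

#' Pair device and diary nights
#'
#' Inner-joins app-recorded and self-reported records on participant and wake
#' date, attaches the weekend-night label and the elapsed-seconds scale used
#' by all indicator arithmetic: seconds since midnight of the wake date, so an
#' onset before midnight is negative and continuity across midnight is kept
#' within each night. Unmatched nights are counted in attribute
#' `"n_unmatched"`.
#'
#' @param app,self either `sleep_series` objects, lists of them, or data
#'   frames as from [as.data.frame.sleep_series()] (columns `participant_id`,
#'   `wake_date`, `onset`, `wake`, `midpoint`, `tst`).
#' @param cfg a [rhythm_config()].
#' @return a `data.frame` of night pairs, one row per matched
#'   (participant, wake date).
#' @export
pair_nights <- function(app, self, cfg = rhythm_config()) {
  a <- records_frame(app)
  b <- records_frame(self)
  keep <- c("participant_id", "wake_date", "onset", "wake", "midpoint", "tst")
  m <- merge(a[keep], b[keep], by = c("participant_id", "wake_date"),
             suffixes = c("_app", "_self"))
  m <- m[order(m$participant_id, m$wake_date), , drop = FALSE]
  rownames(m) <- NULL
  for (ind in c("onset", "wake", "midpoint")) {
    for (src in c("app", "self")) {
      col <- paste0(ind, "_", src)
      m[[paste0(col, "_elapsed")]] <-
        elapsed_since_midnight(m[[col]], m$wake_date, cfg$tz)
    }
  }
  m$is_weekend_night <- is_weekend_night(m$wake_date, m$onset_app, cfg)
  m$overlap <- overlap_ratio(m$onset_app, m$wake_app, m$onset_self,
                             m$wake_self)
  attr(m, "n_unmatched") <- (nrow(a) - nrow(m)) + (nrow(b) - nrow(m))
  m
}

records_frame <- function(x) {
  if (inherits(x, "sleep_series")) return(as.data.frame(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, records_frame)))
  stop(rk_input_error("expected a sleep_series, list of them, or data.frame"))
}

#' Paired differences of sleep indicators
#'
#' For each of onset, wake, midpoint (elapsed seconds since midnight of the
#' wake date) and total sleep time (seconds), the mean device-minus-diary
#' difference with a two-tailed paired t test. The default unit of analysis is
#' the participant: per-participant means over their nights are computed
#' first and the t test pairs those means (n = number of participants);
#' `unit = "night"` pools all nights instead. Zero variance of the paired
#' differences is reported as a degenerate test (t and p `NA`, flag set)
#' rather than an infinite statistic.
#'
#' @param pairs night pairs from [pair_nights()] (or a data frame with the
#'   same `*_elapsed` / `tst_*` columns and `participant_id`).
#' @param unit `"participant"` (default) or `"night"`.
#' @return a `data.frame` with one row per indicator: `mean_app`, `mean_self`,
#'   `mean_diff`, `t`, `df`, `p`, `degenerate`, `n`.
#' @export
paired_indicator_differences <- function(pairs,
                                         unit = c("participant", "night")) {
  unit <- match.arg(unit)
  cols <- list(onset = c("onset_app_elapsed", "onset_self_elapsed"),
               wake = c("wake_app_elapsed", "wake_self_elapsed"),
               midpoint = c("midpoint_app_elapsed", "midpoint_self_elapsed"),
               tst = c("tst_app", "tst_self"))
  out <- lapply(names(cols), function(ind) {
    a <- pairs[[cols[[ind]][1]]]
    b <- pairs[[cols[[ind]][2]]]
    if (unit == "participant") {
      a <- tapply(a, pairs$participant_id, mean)
      b <- tapply(b, pairs$participant_id, mean)
    }
    if (length(a) < 2)
      stop(rk_input_error("paired_indicator_differences: need >= 2 pairs"))
    d <- a - b
    if (stats::sd(d) == 0) {
      data.frame(indicator = ind, mean_app = mean(a), mean_self = mean(b),
                 mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
                 p = NA_real_, degenerate = TRUE, n = length(d))
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(indicator = ind, mean_app = mean(a), mean_self = mean(b),
                 mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 degenerate = FALSE, n = length(d))
    }
  })
  do.call(rbind, out)
}

#' Correlation of device and diary midpoints of sleep
#'
#' Pearson correlation between app-recorded and self-reported midpoint of
#' sleep on the elapsed-seconds scale. `scope = "overall"` pools every pair;
#' `scope = "per_day"` computes one coefficient per wake date across
#' participants (the daily circadian-agreement track). Coefficients are
#' undefined (NA, with a reason) below 3 pairs or under zero variance.
#'
#' @param pairs night pairs from [pair_nights()].
#' @param scope `"overall"` or `"per_day"`.
#' @return for `"overall"`, a one-row `data.frame` (`r`, `n`, `reason`); for
#'   `"per_day"`, one row per wake date.
#' @export
midpoint_correlation <- function(pairs, scope = c("overall", "per_day")) {
  scope <- match.arg(scope)
  one <- function(a, b) {
    if (length(a) < 3)
      return(data.frame(r = NA_real_, n = length(a), reason = "fewer than 3 pairs"))
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(r = NA_real_, n = length(a), reason = "zero variance"))
    data.frame(r = stats::cor(a, b), n = length(a), reason = NA_character_)
  }
  if (scope == "overall")
    return(one(pairs$midpoint_app_elapsed, pairs$midpoint_self_elapsed))
  sp <- split(pairs, pairs$wake_date)
  out <- do.call(rbind, lapply(sp, function(p)
    one(p$midpoint_app_elapsed, p$midpoint_self_elapsed)))
  out <- cbind(wake_date = as.Date(names(sp)), out)
  rownames(out) <- NULL
  out
}

#' Social jetlag
#'
#' Absolute difference between the mean weekend-night and mean weeknight
#' midpoint of sleep, in minutes, for one participant's series (or one
#' participant's half of a pairs frame). The absolute value makes the measure
#' invariant to which class is labelled "weekend".
#'
#' @param x a `sleep_series`, or a `data.frame` with columns
#'   `midpoint_elapsed` and `is_weekend_night`.
#' @param cfg a [rhythm_config()] (used when `x` is a series).
#' @return minutes (scalar).
#' @export
social_jetlag <- function(x, cfg = NULL) {
  if (inherits(x, "sleep_series")) {
    cfg <- cfg %||% x$config
    r <- x$records
    x <- data.frame(
      midpoint_elapsed = elapsed_since_midnight(r$midpoint, r$wake_date,
                                                cfg$tz),
      is_weekend_night = is_weekend_night(r$wake_date, r$onset, cfg))
  }
  wk <- x$midpoint_elapsed[!x$is_weekend_night]
  we <- x$midpoint_elapsed[x$is_weekend_night]
  if (!length(wk) || !length(we))
    stop(rk_input_error("social_jetlag: need at least one night of each class"))
  abs(mean(we) - mean(wk)) / 60
}

#' Compare device and diary social jetlag across a cohort
#'
#' Per-participant social jetlag from the device records and from the diary,
#' compared by a paired t test across participants. Participants missing one
#' night class in either source are excluded pairwise.
#'
#' @param pairs night pairs from [pair_nights()].
#' @return a list with `per_participant` (data frame: `participant_id`,
#'   `jetlag_app`, `jetlag_self` in minutes), `mean_app`, `mean_self`, `t`,
#'   `df`, `p`, `degenerate`, `n_excluded`.
#' @export
social_jetlag_comparison <- function(pairs) {
  sp <- split(pairs, pairs$participant_id)
  per <- lapply(sp, function(p) {
    jl <- function(col) tryCatch(
      social_jetlag(data.frame(midpoint_elapsed = p[[col]],
                               is_weekend_night = p$is_weekend_night)),
      rk_input_error = function(e) NA_real_)
    data.frame(participant_id = p$participant_id[1],
               jetlag_app = jl("midpoint_app_elapsed"),
               jetlag_self = jl("midpoint_self_elapsed"))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ok <- stats::complete.cases(per)
  test <- paired_test(per$jetlag_app[ok], per$jetlag_self[ok])
  c(list(per_participant = per, n_excluded = sum(!ok)), test)
}

# shared paired-t wrapper with the degenerate (zero-variance) guard
paired_test <- function(a, b) {
  if (length(a) < 2)
    stop(rk_input_error("paired test: need >= 2 participants"))
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(mean_app = mean(a), mean_self = mean(b), mean_diff = mean(d),
                t = NA_real_, df = length(d) - 1, p = NA_real_,
                degenerate = TRUE, n = length(d)))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(mean_app = mean(a), mean_self = mean(b), mean_diff = mean(d),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       degenerate = FALSE, n = length(d))
}

#' Sleep-efficiency proxy
#'
#' Treating the diary interval as time in bed and the device interval as
#' sleep, efficiency is estimated as `tst_app / tst_self`. The ratio is not
#' clamped; values above 1 (device interval longer than the diary's) are
#' possible and flagged by the caller.
#'
#' @param tst_app,tst_self total sleep times in seconds, both positive.
#' @return numeric ratio(s).
#' @export
sleep_efficiency <- function(tst_app, tst_self) {
  if (any(tst_self <= 0) || any(tst_app <= 0))
    stop(rk_input_error("sleep_efficiency: total sleep times must be positive"))
  tst_app / tst_self
}

#' Weeknight vs weekend-night overlap comparison
#'
#' Per-participant mean overlap ratio on weeknights and on weekend nights,
#' compared by a paired t test across participants (participants lacking one
#' class are excluded pairwise; at least two complete participants are
#' required).
#'
#' @param pairs night pairs from [pair_nights()].
#' @return a list: `per_participant`, `mean_weeknight`, `mean_weekend`, `t`,
#'   `df`, `p`, `degenerate`, `n_excluded`.
#' @export
compare_weeknight_weekend_overlap <- function(pairs) {
  sp <- split(pairs, pairs$participant_id)
  per <- do.call(rbind, lapply(sp, function(p) data.frame(
    participant_id = p$participant_id[1],
    overlap_weeknight = if (any(!p$is_weekend_night))
      mean(p$overlap[!p$is_weekend_night]) else NA_real_,
    overlap_weekend = if (any(p$is_weekend_night))
      mean(p$overlap[p$is_weekend_night]) else NA_real_)))
  rownames(per) <- NULL
  ok <- stats::complete.cases(per)
  test <- paired_test(per$overlap_weeknight[ok], per$overlap_weekend[ok])
  names(test)[match(c("mean_app", "mean_self"), names(test))] <-
    c("mean_weeknight", "mean_weekend")
  c(list(per_participant = per, n_excluded = sum(!ok)), test)
}

#' Full device-vs-diary agreement report
#'
#' Computes the complete validation battery for a cohort: per-night overlap
#' ratios and their mean, paired indicator differences (participant-level by
#' default), overall and per-day midpoint correlations, the social-jetlag
#' comparison, the weeknight/weekend overlap comparison, and the mean
#' sleep-efficiency proxy.
#'
#' @param app,self as in [pair_nights()].
#' @param cfg a [rhythm_config()].
#' @param unit unit of analysis for the paired tests, see
#'   [paired_indicator_differences()].
#' @return an object of class `sleep_agreement`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_participants = 4, n_days = 8, seed = 3))
#' fits <- lapply(names(sim$events), function(id)
#'   detect_sleep_series(sim$events[[id]], id))
#' selfs <- lapply(split(sim$self_report, sim$self_report$participant_id),
#'   function(d) self_report_series(d, d$participant_id[1]))
#' rep <- sleep_agreement(fits, selfs)
#' rep
sleep_agreement <- function(app, self, cfg = rhythm_config(),
                            unit = c("participant", "night")) {
  unit <- match.arg(unit)
  pairs <- pair_nights(app, self, cfg)
  if (!nrow(pairs))
    stop(rk_input_error("sleep_agreement: no matched (participant, wake_date) pairs"))
  eff <- sleep_efficiency(pairs$tst_app, pairs$tst_self)
  multi <- length(unique(pairs$participant_id)) >= 2
  both_classes <- any(pairs$is_weekend_night) && any(!pairs$is_weekend_night)
  structure(list(
    pairs = pairs,
    n_pairs = nrow(pairs),
    n_unmatched = attr(pairs, "n_unmatched"),
    mean_overlap = mean(pairs$overlap),
    differences = paired_indicator_differences(pairs, unit),
    correlation_overall = midpoint_correlation(pairs, "overall"),
    correlation_per_day = midpoint_correlation(pairs, "per_day"),
    social_jetlag = if (multi && both_classes)
      social_jetlag_comparison(pairs) else NULL,
    weekend_overlap = if (multi && both_classes)
      compare_weeknight_weekend_overlap(pairs) else NULL,
    mean_efficiency = mean(eff),
    n_efficiency_over_1 = sum(eff > 1),
    unit = unit, config = cfg), class = "sleep_agreement")
}

#' @export
print.sleep_agreement <- function(x, digits = 2, ...) {
  cat(sprintf("Device vs diary sleep agreement: %d night pairs (%d unmatched)\n",
              x$n_pairs, x$n_unmatched))
  cat(sprintf("  mean overlap ratio: %.1f%%\n", x$mean_overlap))
  d <- x$differences
  cat(sprintf("  paired differences (device - diary, %s level, n = %d):\n",
              x$unit, d$n[1]))
  for (i in seq_len(nrow(d)))
    cat(sprintf("    %-8s %+8.1f s   t = %s, p = %s%s\n", d$indicator[i],
                d$mean_diff[i],
                if (d$degenerate[i]) "undef." else sprintf("%.2f", d$t[i]),
                if (d$degenerate[i]) "undef." else format.pval(d$p[i], digits = 3),
                if (d$degenerate[i]) "  (zero-variance differences)" else ""))
  co <- x$correlation_overall
  cat(sprintf("  midpoint correlation: overall r = %.3f (N = %d)",
              co$r, co$n))
  pd <- x$correlation_per_day$r
  if (any(!is.na(pd)))
    cat(sprintf("; daily r in [%.2f, %.2f] over %d day(s)\n",
                min(pd, na.rm = TRUE), max(pd, na.rm = TRUE), sum(!is.na(pd))))
  else cat("\n")
  if (!is.null(x$social_jetlag)) {
    sj <- x$social_jetlag
    cat(sprintf("  social jetlag: device %.1f min vs diary %.1f min (paired p = %s)\n",
                sj$mean_app, sj$mean_self,
                if (sj$degenerate) "undef." else format.pval(sj$p, digits = 3)))
  }
  if (!is.null(x$weekend_overlap)) {
    wo <- x$weekend_overlap
    cat(sprintf("  overlap weeknight %.1f%% vs weekend %.1f%% (paired p = %s)\n",
                wo$mean_weeknight, wo$mean_weekend,
                if (wo$degenerate) "undef." else format.pval(wo$p, digits = 3)))
  }
  cat(sprintf("  mean sleep efficiency (TST_app/TST_self): %.3f (%d pair(s) > 1)\n",
              x$mean_efficiency, x$n_efficiency_over_1))
  invisible(x)
}

#' @export
summary.sleep_agreement <- function(object, ...) object

#' Plot the cohort circadian-rhythm track
#'
#' Per-day cohort mean midpoint of sleep with 1-SD error bars for device and
#' diary records, over the study days.
#'
#' @param x a `sleep_agreement`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sleep_agreement <- function(x, ...) {
  p <- x$pairs
  agg <- function(col) {
    m <- tapply(p[[col]], p$wake_date, mean) / 3600
    s <- tapply(p[[col]], p$wake_date, stats::sd) / 3600
    list(m = m, s = s)
  }
  a <- agg("midpoint_app_elapsed"); b <- agg("midpoint_self_elapsed")
  d <- as.Date(names(a$m))
  ylim <- range(c(a$m - a$s, a$m + a$s, b$m - b$s, b$m + b$s), na.rm = TRUE)
  graphics::plot(d, a$m, type = "b", pch = 19, ylim = ylim, col = "steelblue",
                 xlab = "wake date",
                 ylab = "midpoint of sleep (h after midnight)",
                 main = "Cohort midpoint of sleep: device vs diary", ...)
  graphics::arrows(d, a$m - a$s, d, a$m + a$s, angle = 90, code = 3,
                   length = 0.03, col = "steelblue")
  graphics::lines(d + 0.15, b$m, type = "b", pch = 1, col = "tomato")
  graphics::arrows(d + 0.15, b$m - b$s, d + 0.15, b$m + b$s, angle = 90,
                   code = 3, length = 0.03, col = "tomato")
  graphics::legend("topright", c("device", "diary"), pch = c(19, 1),
                   col = c("steelblue", "tomato"), bty = "n")
  invisible(x)
}
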