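#' Extract constant-dose segments from a medication record
#'
#' Finds maximal windows during which every drug's infusion rate is constant
#' (no recorded rate event of any drug inside the window), keeps windows of
#' at least `min_raw_h` hours, discards any window containing a bolus, trims
#' `guard_min` minutes from each end (data near a recorded change or the
#' record boundaries are excluded), and keeps the segment only if the median
#' BSP of its valid epochs is at least `min_median_bsp`. With the defaults a
#' 2-hour raw window yields a 1-hour segment, the minimum possible length.
#'
#' @param meds Medication tibble (`drug`, `time_s`, `event`, `value`;
#'   optional `subject_id`).
#' @param traj A `bsp_traj` for the same record (shared time origin).
#' @param min_raw_h Minimum raw constant-rate window, hours.
#' @param guard_min Guard time trimmed at each end, minutes.
#' @param min_median_bsp Minimum median BSP of the trimmed segment.
#' @return A tibble with one row per segment: `subject_id`, `start_s`,
#'   `end_s` (trimmed, half-open), `duration_h`, `dose_combo` (rates rounded
#'   to 0.1 mg/kg/hr), `median_bsp`, `n_epochs`, and a list-column `data`
#'   of per-epoch (`t_start`, `bsp`) tibbles.
#' @export
extract_constant_segments <- function(meds, traj, min_raw_h = 2,
                                      guard_min = 30, min_median_bsp = 0.05) {
  validate_regimen(meds)
  subject <- if ("subject_id" %in% names(meds) && nrow(meds) > 0) {
    meds$subject_id[1]
  } else NA_character_
  dur_s <- max(traj$t_start) + (attr(traj, "epoch_len") %||% 1)
  rate_times <- sort(unique(meds$time_s[meds$event == "rate"]))
  breaks <- sort(unique(c(0, rate_times[rate_times < dur_s], dur_s)))
  guard_s <- guard_min * 60
  bolus_times <- meds$time_s[meds$event == "bolus"]
  drugs <- unique(meds$drug)

  out <- list()
  for (b in seq_len(length(breaks) - 1)) {
    s <- breaks[b]; e <- breaks[b + 1]
    if (e - s < min_raw_h * 3600) next
    if (any(bolus_times >= s & bolus_times < e)) next
    s2 <- s + guard_s; e2 <- e - guard_s
    if (e2 <= s2) next
    sel <- traj$t_start >= s2 & traj$t_start < e2 & traj$N > 0
    if (!any(sel)) next
    bsp <- traj$bsp[sel]
    med_bsp <- median(bsp)
    if (med_bsp < min_median_bsp) next
    rates <- vapply(drugs, function(d) rate_at(meds, d, s), numeric(1))
    out[[length(out) + 1]] <- tibble(
      subject_id = subject,
      start_s = s2, end_s = e2, duration_h = (e2 - s2) / 3600,
      dose_combo = dose_combo_key(drugs, rates),
      median_bsp = med_bsp, n_epochs = sum(sel),
      data = list(tibble(t_start = traj$t_start[sel], bsp = bsp))
    )
  }
  if (length(out) == 0) {
    return(tibble(subject_id = character(), start_s = numeric(),
                  end_s = numeric(), duration_h = numeric(),
                  dose_combo = character(), median_bsp = numeric(),
                  n_epochs = integer(), data = list()))
  }
  dplyr::bind_rows(out)
}

# canonical key: drugs with non-zero rate, rounded to 0.1 mg/kg/hr, sorted
dose_combo_key <- function(drugs, rates) {
  r <- round(rates, 1)
  keep <- r > 0
  if (!any(keep)) return("none")
  paste(sort(sprintf("%s=%.1f", drugs[keep], r[keep])), collapse = "+")
}

# trend taxonomy for one segment's OLS fit
drift_trend <- function(slope_per_day, bsp_sd, slope_thresh = 2.4,
                        sd_thresh = 0.1) {
  if (slope_per_day > slope_thresh) "increasing"
  else if (slope_per_day < -slope_thresh) "decreasing"
  else if (bsp_sd > sd_thresh) "varying"
  else "constant"
}

#' Fit linear BSP drift within constant-dose segments
#'
#' Ordinary least squares of BSP against time (in days) within each segment,
#' capturing within-patient drift at constant dose. The four-way trend label
#' follows a slope/scatter rule: `constant` if |slope| <= `slope_thresh`
#' (default 2.4/day, i.e. 0.1 BSP units per hour) and the BSP standard
#' deviation is <= `sd_thresh`; `increasing`/`decreasing` by slope sign when
#' |slope| exceeds the threshold; otherwise `varying`.
#'
#' @param segments Segment tibble from [extract_constant_segments()], or any
#'   tibble with a `data` list-column of (`t_start`, `bsp`) tibbles.
#' @param slope_thresh Trend threshold on |slope|, BSP units per day.
#' @param sd_thresh Scatter threshold on the BSP standard deviation.
#' @return The input tibble with columns `slope_per_day`, `intercept`,
#'   `bsp_sd`, `trend` added.
#' @export
fit_drift <- function(segments, slope_thresh = 2.4, sd_thresh = 0.1) {
  stopifnot("data" %in% names(segments))
  fits <- purrr::map(segments$data, function(d) {
    if (length(unique(d$t_start)) < 2) {
      abort("Drift regression needs at least 2 distinct time points.")
    }
    days <- (d$t_start - d$t_start[1]) / 86400
    fit <- lm(d$bsp ~ days)
    slope <- unname(coef(fit)[2])
    s <- sd(d$bsp)
    list(slope = slope, intercept = unname(coef(fit)[1]), sd = s,
         trend = drift_trend(slope, s, slope_thresh, sd_thresh))
  })
  segments$slope_per_day <- purrr::map_dbl(fits, "slope")
  segments$intercept <- purrr::map_dbl(fits, "intercept")
  segments$bsp_sd <- purrr::map_dbl(fits, "sd")
  segments$trend <- purrr::map_chr(fits, "trend")
  segments
}

#' Convert a BSP drift slope to a change over an interval
#'
#' A slope of `s` BSP units per day corresponds to a change of
#' `s * interval / 1440` over `interval` minutes. For example the largest
#' drift a patient may show, 6.77/day, is about 0.14 every 30 minutes —
#' enough to leave a 0.15-wide tolerance from its center between two
#' half-hourly dose adjustments.
#'
#' @param slope_per_day Drift slope, BSP units per day.
#' @param interval_min Interval length in minutes.
#' @return BSP change over the interval.
#' @export
slope_to_delta <- function(slope_per_day, interval_min) {
  if (any(interval_min <= 0)) abort("`interval_min` must be positive.")
  slope_per_day * interval_min / 1440
}

#' Group constant-dose segments by matched dose combination
#'
#' Segments from different subjects whose per-drug weight-normalized rates
#' agree exactly after rounding to 0.1 mg/kg/hr form a dose-match group.
#' Combinations observed in fewer than two distinct subjects are dropped.
#' For every subject pair within a group the exceedance probability between
#' their pooled BSP samples is computed, with the lower-median subject as
#' the reference, so the probability is that a sample from the lower-median
#' distribution falls below one from the higher-median distribution.
#'
#' @param segments Segment tibble across subjects (needs `subject_id`,
#'   `dose_combo`, `data`).
#' @return A tibble (`dose_combo`, `subject_lo`, `subject_hi`, `median_lo`,
#'   `median_hi`, `n_lo`, `n_hi`, `prob`), one row per subject pair.
#' @export
match_dose_groups <- function(segments) {
  stopifnot(all(c("subject_id", "dose_combo", "data") %in% names(segments)))
  segments <- segments[segments$dose_combo != "none", , drop = FALSE]
  out <- list()
  for (combo in unique(segments$dose_combo)) {
    sub <- segments[segments$dose_combo == combo, , drop = FALSE]
    subjects <- unique(sub$subject_id)
    if (length(subjects) < 2) next
    pooled <- lapply(subjects, function(sid) {
      unlist(lapply(sub$data[sub$subject_id == sid], function(d) d$bsp))
    })
    names(pooled) <- subjects
    pairs <- utils::combn(subjects, 2, simplify = FALSE)
    for (pr in pairs) {
      x <- pooled[[pr[1]]]; y <- pooled[[pr[2]]]
      if (median(x) <= median(y)) {
        lo <- pr[1]; hi <- pr[2]
      } else {
        lo <- pr[2]; hi <- pr[1]
        tmp <- x; x <- y; y <- tmp
      }
      out[[length(out) + 1]] <- tibble(
        dose_combo = combo, subject_lo = lo, subject_hi = hi,
        median_lo = median(x), median_hi = median(y),
        n_lo = length(x), n_hi = length(y),
        prob = exceedance_probability(x, y))
    }
  }
  if (length(out) == 0) {
    return(tibble(dose_combo = character(), subject_lo = character(),
                  subject_hi = character(), median_lo = numeric(),
                  median_hi = numeric(), n_lo = integer(), n_hi = integer(),
                  prob = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Exceedance probability between two BSP sample sets
#'
#' The probability that a sample drawn from `x` is smaller than one drawn
#' from `y`, `P(X < Y) + 0.5 * P(X = Y)` over all ordered pairs (the
#' Mann-Whitney U statistic scaled to a probability). Computed exactly for
#' any sample sizes via sorted-rank counting. Callers comparing
#' distributions should pass the lower-median set as `x`.
#'
#' @param x,y Numeric sample sets (non-empty).
#' @return Probability in `[0, 1]`; `exceedance_probability(x, y) ==
#'   1 - exceedance_probability(y, x)` in the absence of ties.
#' @export
exceedance_probability <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both sample sets must be non-empty.")
  }
  xs <- sort(x)
  n_le <- findInterval(y, xs)                  # count of x <= each y
  n_lt <- findInterval(y, xs, left.open = TRUE) # count of x <  each y
  (sum(n_lt) + 0.5 * sum(n_le - n_lt)) / (length(x) * length(y))
}
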