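test_that("constant-dose segment extraction applies trim and bolus rules", {
  traj <- make_traj(rep(0.8, 12 * 3600)) # 12 h of epochs at BSP 0.8

  # one rate step, constant for 10 h between changes: 9 h after trimming
  meds <- tibble::tibble(subject_id = "S1", drug = "propofol",
                         time_s = c(0, 10 * 3600), event = "rate",
                         value = c(2, 3))
  seg <- extract_constant_segments(meds, traj)
  expect_equal(nrow(seg), 2) # 10 h window and the 2 h tail
  expect_equal(seg$start_s[1], 1800)
  expect_equal(seg$end_s[1], 10 * 3600 - 1800)
  expect_equal(seg$duration_h[1], 9)
  expect_equal(seg$dose_combo, c("propofol=2.0", "propofol=3.0"))

  # exactly 2 h raw -> exactly 1 h trimmed, kept (the minimum length)
  traj2 <- make_traj(rep(0.8, 4 * 3600))
  meds2 <- tibble::tibble(subject_id = "S1", drug = "propofol",
                          time_s = c(0, 7200), event = "rate", value = c(2, 0))
  seg2 <- extract_constant_segments(meds2, traj2)
  expect_equal(seg2$duration_h[1], 1)

  # a bolus inside the raw window discards the whole segment
  meds3 <- dplyr::bind_rows(
    const_meds(2),
    tibble::tibble(subject_id = "S1", drug = "propofol", time_s = 5000,
                   event = "bolus", value = 1))
  traj3 <- make_traj(rep(0.8, 2.5 * 3600))
  expect_equal(nrow(extract_constant_segments(meds3, traj3)), 0)

  # low-BSP segments (median < 0.05) are excluded
  low <- make_traj(rep(0.01, 4 * 3600))
  expect_equal(nrow(extract_constant_segments(const_meds(2), low)), 0)

  # raw windows below 2 h never qualify
  short <- make_traj(rep(0.8, 3600))
  expect_equal(nrow(extract_constant_segments(const_meds(2), short)), 0)
})

test_that("segments never reach within the guard of a rate change", {
  set.seed(23)
  traj <- make_traj(rep(0.7, 24 * 3600))
  for (rep_i in 1:5) {
    times <- sort(c(0, sample(seq(600, 23 * 3600, by = 600), 6)))
    meds <- tibble::tibble(subject_id = "S", drug = "propofol",
                           time_s = times, event = "rate",
                           value = round(runif(length(times), 0.5, 4), 1))
    seg <- extract_constant_segments(meds, traj)
    if (nrow(seg) == 0) next
    for (i in seq_len(nrow(seg))) {
      gaps <- abs(c(times, 24 * 3600) - seg$start_s[i])
      gaps2 <- abs(c(times, 24 * 3600) - seg$end_s[i])
      expect_true(min(gaps) >= 1800 && min(gaps2) >= 1800)
    }
  }
})

test_that("drift regression recovers slopes and labels trends", {
  # noiseless line at 2.4/day
  tt <- seq(0, 8 * 3600 - 1)
  line <- tibble::tibble(subject_id = "S", dose_combo = "propofol=2.0",
                         data = list(tibble::tibble(
                           t_start = tt, bsp = 0.3 + 2.4 * tt / 86400)))
  f <- fit_drift(line)
  expect_equal(f$slope_per_day, 2.4, tolerance = 1e-9)
  expect_equal(f$intercept, 0.3, tolerance = 1e-9)

  flat <- tibble::tibble(data = list(tibble::tibble(
    t_start = tt, bsp = rep(0.8, length(tt)))))
  ff <- fit_drift(flat)
  expect_equal(ff$slope_per_day, 0)
  expect_equal(ff$trend, "constant")

  # slope 3.0/day plus N(0, 0.05) noise over 8 h of 1 s epochs
  set.seed(29)
  noisy <- tibble::tibble(data = list(tibble::tibble(
    t_start = tt, bsp = 0.3 + 3.0 * tt / 86400 + rnorm(length(tt), sd = 0.05))))
  fn <- fit_drift(noisy)
  expect_lt(abs(fn$slope_per_day - 3.0), 0.3)
  expect_equal(fn$trend, "increasing")

  # high scatter at small slope reads as "varying"
  set.seed(31)
  wob <- tibble::tibble(data = list(tibble::tibble(
    t_start = tt, bsp = 0.5 + 0.3 * sin(2 * pi * tt / (4 * 3600)))))
  expect_equal(fit_drift(wob)$trend, "varying")

  expect_error(
    fit_drift(tibble::tibble(data = list(tibble::tibble(t_start = 1,
                                                        bsp = 0.5)))),
    "2 distinct time points")
})

test_that("slope-to-interval conversion is exact arithmetic", {
  expect_equal(slope_to_delta(6.77, 30), 6.77 * 30 / 1440)
  expect_equal(round(slope_to_delta(6.77, 30), 4), 0.1410)
  expect_lte(slope_to_delta(6.77, 30), 0.15)
  expect_equal(slope_to_delta(0, 45), 0)
  expect_equal(slope_to_delta(2.4, 60), 0.1)
  expect_error(slope_to_delta(1, 0), "positive")
})

test_that("dose matching groups identical rounded combinations", {
  seg <- function(sid, combo, bsp) {
    tibble::tibble(subject_id = sid, dose_combo = combo,
                   data = list(tibble::tibble(t_start = seq_along(bsp),
                                              bsp = bsp)))
  }
  segs <- dplyr::bind_rows(
    seg("A", "propofol=3.0", rep(0.5, 10)),
    seg("B", "propofol=3.0", rep(0.7, 10)),
    seg("C", "propofol=2.9", rep(0.6, 10)))
  g <- match_dose_groups(segs)
  expect_equal(nrow(g), 1)
  expect_setequal(c(g$subject_lo, g$subject_hi), c("A", "B"))

  # different drug sets never match
  segs2 <- dplyr::bind_rows(
    seg("A", "midazolam=0.1+propofol=3.0", rep(0.5, 5)),
    seg("B", "propofol=3.0", rep(0.6, 5)))
  expect_equal(nrow(match_dose_groups(segs2)), 0)

  # three subjects at one combo: all three pairwise comparisons
  segs3 <- dplyr::bind_rows(
    seg("A", "propofol=2.0", runif(10)),
    seg("B", "propofol=2.0", runif(10)),
    seg("C", "propofol=2.0", runif(10)))
  expect_equal(nrow(match_dose_groups(segs3)), 3)
})

test_that("exceedance probability equals the pair-count definition", {
  expect_equal(exceedance_probability(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(exceedance_probability(c(1, 2), c(5, 6)), 1)
  expect_equal(exceedance_probability(c(1, 3), c(2, 4)), 0.75)
  expect_error(exceedance_probability(numeric(0), 1), "non-empty")

  set.seed(37)
  for (i in 1:20) {
    x <- round(runif(sample(2:30, 1)), 2) # rounding forces some ties
    y <- round(runif(sample(2:30, 1)), 2)
    expect_equal(exceedance_probability(x, y), exceedance_brute(x, y))
  }
  # complement property without ties
  x <- rnorm(25); y <- rnorm(40)
  expect_equal(exceedance_probability(x, y),
               1 - exceedance_probability(y, x))
})
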