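#' Pharmacokinetic/pharmacodynamic parameters for one subject
#'
#' A one-effect-compartment linear PK model with a Hill (sigmoid Emax)
#' pharmacodynamic link drives the ground-truth burst suppression probability
#' of a synthetic subject. The effect-site concentration obeys
#' `dCe/dt = k_in * R(t) - k_out * Ce` for a weight-normalized infusion rate
#' `R(t)` (mg/kg/hr); boluses add `dose * k_in` instantaneously. The true BSP
#' is `Ce^gamma / (C50(t)^gamma + Ce^gamma)`, where `log C50` performs a
#' Gaussian random walk with per-hour standard deviation `drift_sd`,
#' producing within-subject drift at constant dose.
#'
#' @param k_in Effect-site gain per (mg/kg/hr) per hour. May be a named
#'   vector with one entry per drug; unnamed scalar applies to all drugs.
#' @param k_out Elimination rate, 1/hour. Default corresponds to a 15-minute
#'   effect-site half-life.
#' @param c50 Effect-site concentration at half-maximal suppression
#'   (arbitrary concentration units).
#' @param gamma Hill coefficient (dimensionless, >= 1).
#' @param drift_sd Per-hour standard deviation of the random walk on
#'   `log C50` (dimensionless, >= 0). 0 disables drift.
#' @return An object of class `pkpd_params`.
#' @export
pkpd_params <- function(k_in = 1, k_out = log(2) / 0.25, c50 = 2.5,
                        gamma = 4, drift_sd = 0) {
  if (any(k_in <= 0)) abort("`k_in` must be positive.")
  if (any(k_out <= 0)) abort("`k_out` must be positive.")
  if (c50 <= 0) abort("`c50` must be positive.")
  if (gamma < 1) abort("`gamma` must be >= 1.")
  if (drift_sd < 0) abort("`drift_sd` must be >= 0.")
  structure(
    list(k_in = k_in, k_out = k_out, c50 = c50, gamma = gamma,
         drift_sd = drift_sd),
    class = "pkpd_params"
  )
}

#' @export
print.pkpd_params <- function(x, ...) {
  cat(sprintf(
    "<pkpd_params> k_in=%s /h per (mg/kg/hr), k_out=%.3g /h, C50=%.3g, gamma=%.3g, drift_sd=%.3g /sqrt(h)\n",
    paste(signif(x$k_in, 3), collapse = "/"), x$k_out[1], x$c50, x$gamma,
    x$drift_sd))
  invisible(x)
}

#' Build an infusion regimen table
#'
#' A regimen is a tibble of medication events in the same shape as the
#' on-disk medication record: one row per event, with `event = "rate"` rows
#' defining piecewise-constant weight-normalized infusion-rate steps (value
#' in mg/kg/hr, each step holding over the half-open interval from its time
#' to the next step of the same drug) and `event = "bolus"` rows giving bolus
#' doses in mg/kg.
#'
#' @param drug Drug name, recycled.
#' @param time_s Event time in seconds from record start.
#' @param event `"rate"` or `"bolus"`.
#' @param value Rate in mg/kg/hr or bolus dose in mg/kg.
#' @return A tibble with columns drug, time_s, event, value.
#' @export
infusion_regimen <- function(drug, time_s, event, value) {
  out <- tibble(drug = as.character(drug), time_s = as.numeric(time_s),
                event = as.character(event), value = as.numeric(value))
  validate_regimen(out)
  out
}

validate_regimen <- function(reg) {
  stopifnot(all(c("drug", "time_s", "event", "value") %in% names(reg)))
  bad_event <- !reg$event %in% c("rate", "bolus")
  if (any(bad_event)) {
    abort(sprintf("Unknown medication event '%s' (row %d).",
                  reg$event[which(bad_event)[1]], which(bad_event)[1]))
  }
  neg <- reg$event == "rate" & reg$value < 0
  if (any(neg)) {
    i <- which(neg)[1]
    abort(sprintf("Negative infusion rate %.3g mg/kg/hr for %s at t=%g s.",
                  reg$value[i], reg$drug[i], reg$time_s[i]))
  }
  if (any(reg$value[reg$event == "bolus"] < 0)) {
    abort("Bolus doses must be >= 0.")
  }
  for (d in unique(reg$drug)) {
    tt <- reg$time_s[reg$drug == d & reg$event == "rate"]
    if (is.unsorted(tt)) {
      abort(sprintf("Rate steps for drug '%s' are not time-ordered.", d))
    }
  }
  invisible(reg)
}

# rate of one drug at arbitrary times (piecewise constant, 0 before first step)
rate_at <- function(reg, drug, times) {
  steps <- reg[reg$drug == drug & reg$event == "rate", , drop = FALSE]
  if (nrow(steps) == 0) return(rep(0, length(times)))
  idx <- findInterval(times, steps$time_s)
  out <- rep(0, length(times))
  out[idx > 0] <- steps$value[idx[idx > 0]]
  out
}

#' Simulate the effect-site concentration and true BSP trajectory
#'
#' Integrates the one-compartment effect-site model exactly over the
#' piecewise-constant regimen (analytic exponential update between rate
#' changes and boluses), then maps concentration to the true burst
#' suppression probability through the Hill function with a drifting C50.
#' Multiple drugs combine additively in effect-site concentration, each with
#' its own `k_in`.
#'
#' @param regimen Regimen tibble, see [infusion_regimen()].
#' @param params A [pkpd_params()] object.
#' @param duration_h Simulated duration in hours.
#' @param dt_s Output grid resolution in seconds (must divide the epoch
#'   length used downstream; the default 1 s matches the default epoch).
#' @param seed Integer seed for the C50 random walk.
#' @return A tibble (`time_s`, `ce`, `c50`, `true_bsp`) with one row per
#'   `dt_s` step; `time_s` is the end of each step so the series has
#'   `duration_h * 3600 / dt_s` rows.
#' @export
simulate_pkpd <- function(regimen, params, duration_h, dt_s = 1, seed = 1) {
  stopifnot(inherits(params, "pkpd_params"))
  if (duration_h <= 0) abort("`duration_h` must be positive.")
  validate_regimen(regimen)
  dur_s <- duration_h * 3600
  n <- as.integer(round(dur_s / dt_s))
  t_grid <- dt_s * seq_len(n)

  drugs <- unique(regimen$drug)
  if (length(drugs) == 0) drugs <- "none"
  k_in <- params$k_in
  k_out <- params$k_out
  pick <- function(v, d, i) {
    if (!is.null(names(v)) && d %in% names(v)) unname(v[d])
    else unname(rep_len(v, i)[i])
  }

  ce_total <- rep(0, n)
  for (di in seq_along(drugs)) {
    d <- drugs[di]
    kin_d <- pick(k_in, d, di)
    kout_d <- pick(k_out, d, di)
    sub <- regimen[regimen$drug == d, , drop = FALSE]
    breaks <- sort(unique(c(0, sub$time_s[sub$time_s < dur_s], dur_s)))
    ce <- numeric(n)
    ce0 <- 0
    for (b in seq_len(length(breaks) - 1)) {
      s <- breaks[b]; e <- breaks[b + 1]
      bol <- sub$value[sub$event == "bolus" & sub$time_s == s]
      if (length(bol)) ce0 <- ce0 + sum(bol) * kin_d
      r <- rate_at(sub, d, s)
      ss <- kin_d * r / kout_d
      in_iv <- which(t_grid > s & t_grid <= e)
      if (length(in_iv)) {
        dt_h <- (t_grid[in_iv] - s) / 3600
        ce[in_iv] <- ss + (ce0 - ss) * exp(-kout_d * dt_h)
      }
      ce0 <- ss + (ce0 - ss) * exp(-kout_d * (e - s) / 3600)
    }
    ce_total <- ce_total + ce
  }

  # seeded Gaussian random walk on log C50, per-hour sd = drift_sd
  if (params$drift_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    inc <- rnorm(n, sd = params$drift_sd * sqrt(dt_s / 3600))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    log_c50 <- log(params$c50) + cumsum(inc)
  } else {
    log_c50 <- rep(log(params$c50), n)
  }
  c50_t <- exp(log_c50)
  true_bsp <- hill_bsp(ce_total, c50_t, params$gamma)
  tibble(time_s = t_grid, ce = ce_total, c50 = c50_t, true_bsp = true_bsp)
}

# Hill dose-response on effect-site concentration
hill_bsp <- function(ce, c50, gamma) {
  ifelse(ce <= 0, 0, 1 / (1 + exp(gamma * (log(c50) - log(ce)))))
}

#' Simulate a binary burst/suppression state sequence
#'
#' Alternating-renewal simulation of the EEG state: burst durations are
#' exponential with mean `mean_burst_s`, suppression durations exponential
#' with mean `mean_burst_s * p / (1 - p)` where `p` is the local true BSP, so
#' the long-run suppressed fraction converges to `p`. All durations are
#' floored at `floor_s` (very short bursts/suppressions are not
#' physiological), which biases occupancy slightly toward the floor ratio at
#' extreme `p`. `p = 0` or `p = 1` hold the corresponding constant state.
#'
#' @param true_bsp Numeric vector of true BSP values on a `dt_s` grid.
#' @param fs Sampling rate of the output sequence, Hz.
#' @param mean_burst_s Mean burst duration, seconds (clinically bursts last
#'   one to two seconds; default 1.5).
#' @param floor_s Minimum state duration, seconds.
#' @param dt_s Grid step of `true_bsp`, seconds.
#' @param seed Integer seed.
#' @return Integer vector of length `length(true_bsp) * dt_s * fs`;
#'   1 = suppression, 0 = burst.
#' @export
simulate_state_sequence <- function(true_bsp, fs, mean_burst_s = 1.5,
                                    floor_s = 0.3, dt_s = 1, seed = 1) {
  if (fs <= 0) abort("`fs` must be positive.")
  if (any(true_bsp < 0 | true_bsp > 1)) abort("`true_bsp` must lie in [0, 1].")
  dur_s <- length(true_bsp) * dt_s
  n_samp <- as.integer(round(dur_s * fs))
  out <- integer(n_samp)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  t <- 0
  p0 <- true_bsp[1]
  state <- if (p0 >= 1) 1L else if (p0 <= 0) 0L else as.integer(runif(1) < p0)
  while (t < dur_s) {
    p <- true_bsp[min(floor(t / dt_s) + 1, length(true_bsp))]
    if (p <= 0) {
      state <- 0L
      dur <- dt_s
      flip <- FALSE
    } else if (p >= 1) {
      state <- 1L
      dur <- dt_s
      flip <- FALSE
    } else {
      mu <- if (state == 1L) mean_burst_s * p / (1 - p) else mean_burst_s
      dur <- max(rexp(1, rate = 1 / mu), floor_s)
      flip <- TRUE
    }
    i0 <- floor(t * fs) + 1
    i1 <- min(floor((t + dur) * fs), n_samp)
    if (i1 >= i0) out[i0:i1] <- state
    t <- t + dur
    if (flip) state <- 1L - state
  }
  out
}

#' Synthesize multichannel burst-suppression EEG from a state sequence
#'
#' Each channel is independent band-limited Gaussian noise (1-30 Hz),
#' amplitude-modulated by the binary state with a 100 ms cross-fade:
#' `burst_rms` microvolts RMS during bursts, `supp_rms` during suppressions.
#' Optional high-amplitude artifacts (600 uV half-sine transients of 200 ms,
#' added on every channel) exercise the amplitude-based epoch rejection.
#'
#' @param state_seq Integer 0/1 state sequence at `fs` (1 = suppression).
#' @param fs Sampling rate, Hz.
#' @param n_channels Number of channels (>= 1); 19 gives the standard 10-20
#'   montage.
#' @param burst_rms,supp_rms Per-channel RMS amplitude in microvolts during
#'   bursts / suppressions (`burst_rms > supp_rms > 0`).
#' @param artifact_times Numeric vector of artifact onset times in seconds
#'   (or NULL for none).
#' @param seed Integer seed.
#' @return An [eeg_record()].
#' @export
synthesize_eeg <- function(state_seq, fs, n_channels = 19, burst_rms = 25,
                           supp_rms = 2.5, artifact_times = NULL, seed = 1) {
  if (n_channels < 1) abort("`n_channels` must be >= 1.")
  if (!(burst_rms > supp_rms && supp_rms > 0)) {
    abort("Need `burst_rms > supp_rms > 0`.")
  }
  n <- length(state_seq)

  # amplitude envelope with 100 ms moving-average cross-fade
  amp <- ifelse(state_seq == 1L, supp_rms, burst_rms)
  k <- max(1L, as.integer(round(0.1 * fs)))
  if (k > 1) {
    sm <- stats::filter(amp, rep(1 / k, k), sides = 2)
    amp <- ifelse(is.na(sm), amp, as.numeric(sm))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  samples <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    w <- rnorm(n)
    x <- fft_bandpass_vec(w, fs, lo = 1, hi = min(30, fs / 2 - 1))
    x <- x / sqrt(mean(x^2))
    samples[ch, ] <- x * amp
  }

  if (length(artifact_times)) {
    ns_art <- as.integer(round(0.2 * fs))
    pulse <- 600 * sin(pi * seq_len(ns_art) / ns_art)
    for (ta in artifact_times) {
      i0 <- floor(ta * fs) + 1
      idx <- i0:min(i0 + ns_art - 1, n)
      if (length(idx) > 0 && idx[1] <= n) {
        samples[, idx] <- samples[, idx] +
          matrix(pulse[seq_along(idx)], nrow = n_channels, ncol = length(idx),
                 byrow = TRUE)
      }
    }
  }
  eeg_record(samples, fs)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study setting: 35 subjects (15 anoxic-etiology
#' "aRSE", 20 non-anoxic "nRSE"), 19-channel EEG at 256 Hz, propofol-style
#' single-drug regimens with rate adjustments on the hour-scale (the study's
#' median inter-adjustment time was 2 hours), occasional boluses, and
#' log-normal between-subject spread of C50 and k_out producing distinct
#' dose-responses at matched rates. `duration_h = 12` keeps a full default
#' cohort tractable; the study's recordings were longer.
#'
#' @param n_subjects Cohort size.
#' @param n_arse Number of subjects labeled "aRSE" (the rest are "nRSE").
#' @param duration_h Record duration per subject, hours.
#' @param fs EEG sampling rate, Hz.
#' @param n_channels EEG channels.
#' @param dt_s Ground-truth BSP grid step, seconds.
#' @param drug Drug name used in generated regimens.
#' @param rate_range Range (mg/kg/hr) from which each subject's initial
#'   infusion rate is drawn uniformly. The default straddles the
#'   half-maximal rate `c50_median * k_out_median / k_in` (about 6.9 under
#'   the PK defaults), so generated regimens actually titrate subjects
#'   toward burst suppression rather than leaving the whole cohort
#'   unsuppressed.
#' @param adjust_every_h Mean time between rate adjustments, hours.
#' @param bolus_rate_per_h Expected boluses per hour.
#' @param bolus_dose Bolus dose, mg/kg.
#' @param c50_median,c50_cv Median and coefficient of variation of the
#'   log-normal between-subject C50 distribution.
#' @param k_out_median,k_out_cv Median and CV of the log-normal k_out
#'   distribution (1/hour).
#' @param k_in Effect-site gain (shared across subjects).
#' @param gamma Hill coefficient.
#' @param drift_sd Per-hour sd of the within-subject log-C50 random walk.
#' @param mean_burst_s Mean burst duration, seconds.
#' @param burst_rms,supp_rms EEG amplitudes, uV RMS.
#' @param artifact_rate_per_h Expected high-amplitude artifacts per hour.
#' @param intent_start_s Start of the documented burst-suppression intent
#'   period (seconds; the intent period runs to the end of the record).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 35, n_arse = 15, duration_h = 12,
                          fs = 256, n_channels = 19, dt_s = 1,
                          drug = "propofol", rate_range = c(4, 9),
                          adjust_every_h = 2, bolus_rate_per_h = 1 / 12,
                          bolus_dose = 1,
                          c50_median = 2.5, c50_cv = 0.3,
                          k_out_median = log(2) / 0.25, k_out_cv = 0.3,
                          k_in = 1, gamma = 4, drift_sd = 0.05,
                          mean_burst_s = 1.5, burst_rms = 25, supp_rms = 2.5,
                          artifact_rate_per_h = 1, intent_start_s = 1800) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (c50_cv < 0 || k_out_cv < 0) {
    abort("Coefficients of variation must be >= 0.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

# log-normal sampler parameterized by median and coefficient of variation
rlnorm_cv <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = log(median), sd = sdlog))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject PK/PD parameters, builds a stepped infusion regimen,
#' simulates the effect-site concentration and true BSP trajectory, realizes
#' the binary burst/suppression state sequence, and (optionally) synthesizes
#' multichannel EEG. Every output is a pure function of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param eeg Logical; synthesize the (memory-heavy) EEG voltage traces?
#'   When FALSE, subjects carry the state sequence only, which is sufficient
#'   for BSP-level analyses.
#' @return A list of `synthetic_subject` objects. Each carries `subject_id`,
#'   `group`, `params`, `regimen`, `truth` (tibble time_s/ce/c50/true_bsp),
#'   `state_seq`, `eeg` (or NULL), `meds` (medication record with
#'   subject_id), `intent` (intent-period tibble) and `seed`.
#' @export
make_cohort <- function(config = cohort_config(), seed = 1, eeg = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  n <- config$n_subjects
  c50_i <- rlnorm_cv(n, config$c50_median, config$c50_cv)
  kout_i <- rlnorm_cv(n, config$k_out_median, config$k_out_cv)
  subj_seeds <- sample.int(.Machine$integer.max - 10L, 3 * n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  groups <- c(rep("aRSE", min(config$n_arse, n)),
              rep("nRSE", max(0, n - config$n_arse)))
  ids <- ifelse(groups == "aRSE",
                sprintf("A%02d", cumsum(groups == "aRSE")),
                sprintf("N%02d", cumsum(groups == "nRSE")))

  lapply(seq_len(n), function(i) {
    params <- pkpd_params(k_in = config$k_in, k_out = kout_i[i],
                          c50 = c50_i[i], gamma = config$gamma,
                          drift_sd = config$drift_sd)
    reg <- random_regimen(config, subj_seeds[3 * i - 2])
    truth <- simulate_pkpd(reg, params, config$duration_h, config$dt_s,
                           seed = subj_seeds[3 * i - 2])
    state <- simulate_state_sequence(truth$true_bsp, config$fs,
                                     config$mean_burst_s, dt_s = config$dt_s,
                                     seed = subj_seeds[3 * i - 1])
    art <- artifact_times_for(config, subj_seeds[3 * i])
    rec <- if (eeg) {
      synthesize_eeg(state, config$fs, config$n_channels, config$burst_rms,
                     config$supp_rms, artifact_times = art,
                     seed = subj_seeds[3 * i])
    } else NULL
    meds <- dplyr::bind_cols(tibble(subject_id = ids[i]), reg)
    intent <- tibble(subject_id = ids[i],
                     start_s = config$intent_start_s,
                     end_s = config$duration_h * 3600)
    structure(
      list(subject_id = ids[i], group = groups[i], params = params,
           regimen = reg, truth = truth, state_seq = state, eeg = rec,
           meds = meds, intent = intent, artifact_times = art,
           seed = subj_seeds[3 * i - 2], eeg_seed = subj_seeds[3 * i]),
      class = "synthetic_subject"
    )
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s (%s): %.1f h, mean true BSP %.2f, %s\n",
              x$subject_id, x$group, nrow(x$truth) / 3600,
              mean(x$truth$true_bsp),
              if (is.null(x$eeg)) "state sequence only" else "with EEG"))
  invisible(x)
}

# stepped single-drug regimen: initial rate, multiplicative adjustments at
# exponential intervals, Poisson boluses
random_regimen <- function(config, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  dur_s <- config$duration_h * 3600
  t <- 0
  times <- 0
  rate <- stats::runif(1, config$rate_range[1], config$rate_range[2])
  rates <- rate
  repeat {
    t <- t + max(1800, rexp(1, 1 / (config$adjust_every_h * 3600)))
    if (t >= dur_s) break
    rate <- clip(rate * runif(1, 0.8, 1.25),
                 config$rate_range[1] * 0.5, config$rate_range[2] * 1.5)
    times <- c(times, round(t))
    rates <- c(rates, round(rate, 1))
  }
  n_bol <- stats::rpois(1, config$bolus_rate_per_h * config$duration_h)
  reg <- tibble(drug = config$drug, time_s = as.numeric(times),
                event = "rate", value = round(rates, 1))
  if (n_bol > 0) {
    bt <- sort(round(runif(n_bol, 0, dur_s)))
    reg <- dplyr::bind_rows(
      reg, tibble(drug = config$drug, time_s = as.numeric(bt),
                  event = "bolus", value = config$bolus_dose))
  }
  dplyr::arrange(reg, .data$time_s, .data$event)
}

artifact_times_for <- function(config, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 1L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n_art <- stats::rpois(1, config$artifact_rate_per_h * config$duration_h)
  if (n_art == 0) return(numeric(0))
  sort(runif(n_art, 0, config$duration_h * 3600 - 1))
}
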