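test_that("effect-site simulation matches the closed-form step response", {
  pp <- pkpd_params(k_in = 1, k_out = log(2) / 0.25, c50 = 2.5, gamma = 4,
                    drift_sd = 0)

  # no drug, no suppression
  empty <- infusion_regimen("propofol", 0, "rate", 0)
  sim0 <- simulate_pkpd(empty, pp, duration_h = 1, seed = 1)
  expect_true(all(sim0$ce == 0))
  expect_true(all(sim0$true_bsp == 0))

  # constant-rate step: Ce(t) = Ce_ss (1 - exp(-k_out t))
  reg <- infusion_regimen("propofol", 0, "rate", 2)
  sim <- simulate_pkpd(reg, pp, duration_h = 2, seed = 1)
  ss <- 1 * 2 / (log(2) / 0.25)
  closed <- ss * (1 - exp(-(log(2) / 0.25) * sim$time_s / 3600))
  expect_lt(max(abs(sim$ce - closed) / pmax(closed, 1e-12)), 1e-3)

  # at Ce = C50 the Hill response is one half: choose R so Ce_ss = C50
  r_half <- pp$c50 * pp$k_out / pp$k_in
  sim2 <- simulate_pkpd(infusion_regimen("propofol", 0, "rate", r_half), pp,
                        duration_h = 6, seed = 1)
  expect_equal(tail(sim2$ce, 1), pp$c50, tolerance = 1e-6)
  expect_equal(tail(sim2$true_bsp, 1), 0.5, tolerance = 1e-4)

  # bolus adds dose * k_in instantaneously, then decays
  bol <- infusion_regimen("propofol", c(0, 600), c("rate", "bolus"), c(0, 3))
  sim3 <- simulate_pkpd(bol, pp, duration_h = 1, seed = 1)
  expect_equal(sim3$ce[600], 0)
  expect_equal(sim3$ce[601],
               3 * pp$k_in * exp(-pp$k_out * 1 / 3600), tolerance = 1e-10)

  expect_error(
    simulate_pkpd(tibble::tibble(drug = "mdz", time_s = 0, event = "rate",
                                 value = -1), pp, 1),
    "Negative infusion rate")
})

test_that("renewal state sequence reproduces the requested occupancy", {
  expect_true(all(simulate_state_sequence(rep(0, 60), fs = 64, seed = 1) == 0L))
  expect_true(all(simulate_state_sequence(rep(1, 60), fs = 64, seed = 1) == 1L))

  st <- simulate_state_sequence(rep(0.8, 3600), fs = 256, seed = 2)
  expect_length(st, 3600 * 256)
  expect_lt(abs(mean(st) - 0.8), 0.03)

  # runs are not shorter than the duration floor away from the record edges
  r <- rle(st)
  interior <- r$lengths[-c(1, length(r$lengths))]
  expect_true(all(interior >= 0.3 * 256 - 1))

  expect_error(simulate_state_sequence(rep(0.5, 10), fs = 0), "positive")
})

test_that("synthesized EEG has the prescribed per-state amplitudes", {
  st_burst <- rep(0L, 64 * 60)
  eeg_b <- synthesize_eeg(st_burst, fs = 64, n_channels = 3, burst_rms = 25,
                          supp_rms = 2.5, seed = 3)
  rms_b <- sqrt(rowMeans(eeg_b$samples^2))
  expect_true(all(rms_b > 22.5 & rms_b < 27.5))

  st_supp <- rep(1L, 64 * 60)
  eeg_s <- synthesize_eeg(st_supp, fs = 64, n_channels = 3, burst_rms = 25,
                          supp_rms = 2.5, seed = 3)
  rms_s <- sqrt(rowMeans(eeg_s$samples^2))
  expect_true(all(rms_s > 2.25 & rms_s < 2.75))

  # artifact transient exceeds the 500 uV rejection threshold in its epoch
  eeg_a <- synthesize_eeg(rep(0L, 64 * 120), fs = 64, n_channels = 2,
                          artifact_times = 100, seed = 4)
  ep <- 100 * 64 + seq_len(64)
  expect_gt(max(abs(eeg_a$samples[, ep])), 500)
  mask <- reject_artifacts(eeg_a, thresh = 500)
  expect_false(mask[101])

  expect_error(synthesize_eeg(st_burst, fs = 64, n_channels = 0), ">= 1")
  expect_error(synthesize_eeg(st_burst, fs = 64, burst_rms = 2, supp_rms = 5),
               "burst_rms > supp_rms")
})

test_that("cohort generation is deterministic and spreads dose-response", {
  cfg1 <- cohort_config(n_subjects = 1, n_arse = 0, duration_h = 1, fs = 64,
                        c50_cv = 0, k_out_cv = 0, drift_sd = 0)
  s1 <- make_cohort(cfg1, seed = 5, eeg = FALSE)[[1]]
  expect_equal(s1$params$c50, cfg1$c50_median)
  expect_equal(s1$params$k_out, cfg1$k_out_median)

  cfg <- cohort_config(n_subjects = 3, n_arse = 1, duration_h = 1, fs = 64,
                       n_channels = 2)
  a <- make_cohort(cfg, seed = 7, eeg = FALSE)
  b <- make_cohort(cfg, seed = 7, eeg = FALSE)
  expect_identical(lapply(a, function(s) s$truth),
                   lapply(b, function(s) s$truth))
  expect_identical(lapply(a, function(s) s$state_seq),
                   lapply(b, function(s) s$state_seq))
  expect_identical(vapply(a, function(s) s$group, character(1)),
                   c("aRSE", "nRSE", "nRSE"))

  # C50 spread: identical regimen through two sampled parameter sets gives
  # visibly different steady-state true BSP
  cfg2 <- cohort_config(n_subjects = 2, n_arse = 0, duration_h = 1, fs = 64,
                        c50_cv = 0.3, k_out_cv = 0, drift_sd = 0)
  coh <- make_cohort(cfg2, seed = 11, eeg = FALSE)
  # probe at the half-maximal operating point, where C50 spread matters most
  r_half <- cfg2$c50_median * cfg2$k_out_median / cfg2$k_in
  reg <- infusion_regimen("propofol", 0, "rate", r_half)
  ss <- vapply(coh, function(s) {
    tail(simulate_pkpd(reg, s$params, duration_h = 6, seed = 1)$true_bsp, 1)
  }, numeric(1))
  expect_gt(abs(ss[1] - ss[2]), 0.05)

  expect_error(cohort_config(c50_cv = -0.1), ">= 0")
})

test_that("true BSP is monotone in the infusion rate without drift", {
  pp <- pkpd_params(drift_sd = 0)
  ss_bsp <- vapply(c(0.5, 1, 2, 3, 4, 6), function(r) {
    tail(simulate_pkpd(infusion_regimen("propofol", 0, "rate", r), pp,
                       duration_h = 8, seed = 1)$true_bsp, 1)
  }, numeric(1))
  expect_true(all(diff(ss_bsp) > 0))
})
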