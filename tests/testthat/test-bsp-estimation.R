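test_that("epoch counting aggregates the binary signal per half-open epoch", {
  sig <- binary_signal(rep(1L, 256 * 5), fs = 256)
  cnt <- epoch_counts(sig)
  expect_equal(cnt$n, rep(256L, 5))
  expect_equal(cnt$N, rep(256L, 5))

  half <- binary_signal(rep(c(1L, 0L), 256 * 5 / 2), fs = 256)
  expect_equal(epoch_counts(half)$n, rep(128L, 5))

  masked <- binary_signal(rep(1L, 256 * 5), fs = 256,
                          mask = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  cm <- epoch_counts(masked)
  expect_equal(cm$N[2], 0L)
  expect_equal(sum(cm$n), 4 * 256)
})

test_that("the forward filter handles missing data and model symmetry", {
  # prediction-only: constant mean, linearly growing variance
  gap <- make_counts(rep(0L, 50), 0L)
  f <- bsp_filter(gap, sigma_v2 = 0.01, x0 = 0.5, var0 = 1)
  expect_equal(f$bsp, rep(plogis(0.5), 50))
  expect_equal(f$var, 1 + 0.01 * seq_len(50))

  # long constant observations concentrate at the empirical rate
  const <- make_counts(rep(205L, 3600), 256L)
  sm <- bsp_smoother(bsp_filter(const))
  expect_lt(abs(tail(sm$bsp, 1) - 205 / 256), 0.02)

  # complementing the counts (and the start) reflects the trajectory
  set.seed(3)
  n <- rbinom(500, 64, plogis(cumsum(rnorm(500, sd = 0.1))))
  cn <- make_counts(as.integer(n), 64L)
  cc <- make_counts(64L - as.integer(n), 64L)
  f1 <- bsp_filter(cn, x0 = 0.3)
  f2 <- bsp_filter(cc, x0 = -0.3)
  expect_lt(max(abs(f2$bsp - (1 - f1$bsp))), 1e-6)
})

test_that("the smoother reduces variance and centers step responses", {
  const <- make_counts(rep(50L, 200), 64L)
  f <- bsp_filter(const)
  s <- bsp_smoother(f)
  expect_equal(tail(s$bsp, 1), tail(f$bsp, 1))
  expect_equal(tail(s$var, 1), tail(f$var, 1))
  expect_true(all(s$var <= f$var + 1e-12))

  # step 0.2 -> 0.9 at the midpoint: smoothed crossing of 0.55 near the step
  set.seed(5)
  n <- 2000
  p <- c(rep(0.2, n / 2), rep(0.9, n / 2))
  cn <- make_counts(as.integer(rbinom(n, 256, p)), 256L)
  sm <- bsp_smoother(bsp_filter(cn, sigma_v2 = 0.005))
  cross <- which(sm$bsp >= 0.55)[1]
  expect_lt(abs(cross - (n / 2 + 1)), 60)
  expect_true(all(sm$var <= bsp_filter(cn, sigma_v2 = 0.005)$var + 1e-12))
})

test_that("EM recovers the process noise and floors on static data", {
  set.seed(7)
  Tn <- 3600
  x <- cumsum(rnorm(Tn, sd = sqrt(0.01)))
  cn <- make_counts(as.integer(rbinom(Tn, 256, plogis(x))), 256L)
  s_hat <- estimate_sigma_v2(cn)
  expect_gt(s_hat, 0.005)
  expect_lt(s_hat, 0.02)
  expect_identical(s_hat, estimate_sigma_v2(cn)) # deterministic

  flat <- make_counts(rep(205L, Tn), 256L)
  expect_lt(estimate_sigma_v2(flat), 1e-4)

  expect_error(estimate_sigma_v2(make_counts(rep(10L, 50), 64L)),
               "at least 100 valid epochs")
})

test_that("windowed BSR matches steady-state occupancy and tracks the BSP", {
  allsup <- binary_signal(rep(1L, 64 * 120), fs = 64)
  expect_true(all(windowed_bsr(allsup)$bsr == 1))

  # institutional guideline pattern: one 2 s burst per 10 s cycle = 80%
  cyc <- binary_signal(rep(c(rep(0L, 2 * 64), rep(1L, 8 * 64)), 30), fs = 64)
  bsr <- windowed_bsr(cyc, window = 60)
  i <- (60 * 64):(240 * 64)
  expect_lt(max(abs(bsr$bsr[i] - 0.8)), 1e-6)

  # slow drift, independent Bernoulli samples: BSP and BSR nearly coincide
  set.seed(11)
  fs <- 64
  p_t <- 0.5 + 0.1 * seq_len(2 * 3600) / 3600 / 2 # <= 0.1/h drift
  st <- rbinom(length(p_t) * fs, 1, rep(p_t, each = fs))
  sig <- binary_signal(st, fs = fs)
  sm <- bsp_estimate(epoch_counts(sig))
  bsr2 <- windowed_bsr(sig, window = 60)
  at_epoch <- bsr2$bsr[seq(1, length(st), by = fs)]
  skip_edge <- 61:(length(p_t) - 60)
  expect_lt(max(abs(sm$bsp[skip_edge] - at_epoch[skip_edge])), 0.05)
})

test_that("credible bounds stay in [0,1] and masks never shrink them", {
  set.seed(13)
  n <- as.integer(rbinom(300, 64, runif(300)))
  cn <- make_counts(n, 64L)
  cn$N[100:120] <- 0L
  cn$n[100:120] <- 0L
  f <- bsp_filter(cn)
  expect_true(all(f$ci_lo >= 0 & f$ci_lo <= f$bsp))
  expect_true(all(f$ci_hi <= 1 & f$ci_hi >= f$bsp))
  # variance grows monotonically across the missing stretch
  expect_true(all(diff(f$var[100:120]) > 0))
  s <- bsp_smoother(f)
  expect_true(all(s$ci_lo >= 0 & s$ci_hi <= 1))
})

test_that("serial-correlation ESS is estimated from run lengths", {
  # alternating 2 s / 2 s pattern: tau = 1 s, so 0.5 effective obs/epoch
  per <- binary_signal(rep(c(rep(0L, 128), rep(1L, 128)), 40), fs = 64)
  ess <- estimate_epoch_ess(per)
  expect_equal(ess, 0.5, tolerance = 1e-6)
  # iid samples at high rate: ESS is large, correction capped at raw counts
  set.seed(17)
  iid <- binary_signal(rbinom(64 * 600, 1, 0.5), fs = 64)
  expect_gt(estimate_epoch_ess(iid), 10)
  # constant signal carries no alternation information
  expect_true(is.na(estimate_epoch_ess(binary_signal(rep(1L, 640), fs = 64))))
})
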