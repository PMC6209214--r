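test_that("occupancy fractions follow the band boundary conventions", {
  band <- reference_band()
  expect_equal(c(band$lo, band$hi), c(0.65, 0.95))

  on_target <- make_traj(rep(0.8, 100))
  expect_equal(unlist(occupancy_fractions(on_target, band = band)[1, 1:3]),
               c(pt_a = 0, pt_i = 100, pt_b = 0))
  low <- make_traj(rep(0.5, 100))
  expect_equal(unlist(occupancy_fractions(low, band = band)[1, 1:3]),
               c(pt_a = 0, pt_i = 0, pt_b = 100))

  # inclusive at both band edges, strict outside
  edges <- make_traj(c(0.65, 0.95, 0.6499, 0.9501))
  occ <- occupancy_fractions(edges, band = band)
  expect_equal(occ$pt_i, 50)
  expect_equal(occ$pt_a, 25)
  expect_equal(occ$pt_b, 25)

  # uniform ramp over [0,1]: band widths 5% / 30% / 65%
  ramp <- make_traj(seq(0.0005, 0.9995, length.out = 1000))
  occ_r <- occupancy_fractions(ramp, band = band)
  expect_equal(occ_r$pt_a, 5, tolerance = 0.11)
  expect_equal(occ_r$pt_i, 30, tolerance = 0.11)
  expect_equal(occ_r$pt_b, 65, tolerance = 0.11)
  expect_equal(occ_r$pt_a + occ_r$pt_i + occ_r$pt_b, 100)

  # intent restriction and the undefined (not zero) empty case
  intent <- tibble::tibble(start_s = 200, end_s = 300)
  empty <- occupancy_fractions(on_target, intent)
  expect_true(is.na(empty$pt_i))
  expect_equal(empty$n_valid, 0L)
})

test_that("accurate and reliable control labels follow the CI rules", {
  band <- reference_band()
  # CI [0.7, 0.9] always contains the target
  acc <- make_traj(rep(0.8, 50), ci_lo = rep(0.7, 50), ci_hi = rep(0.9, 50))
  lab <- classify_control(acc, band = band)
  expect_true(lab$accurate)

  # CI [0.2, 0.4] never does, and carries no mass near the band
  off <- make_traj(rep(0.3, 50), x = rep(qlogis(0.3), 50),
                   var = rep(0.01, 50),
                   ci_lo = rep(0.2, 50), ci_hi = rep(0.4, 50))
  lab_off <- classify_control(off, band = band)
  expect_false(lab_off$accurate)
  expect_false(lab_off$reliable)

  # posterior ~ Normal(0.8, 0.02) on the probability scale: essentially all
  # mass inside (0.65, 0.95), so control is reliable
  sd_x <- 0.02 / (0.8 * 0.2) # delta method at p = 0.8
  rel <- make_traj(rep(0.8, 50), x = rep(qlogis(0.8), 50),
                   var = rep(sd_x^2, 50))
  expect_true(classify_control(rel, band = band)$reliable)

  expect_error(classify_control(tibble::tibble(bsp = 0.5), band = band),
               "posterior columns")
})

test_that("the Beta posterior has MAP k/n and central 95% interval", {
  expect_equal(beta_posterior(0, 10)$map, 0)
  expect_equal(beta_posterior(10, 10)$map, 1)
  p <- beta_posterior(12, 19)
  expect_equal(p$map, 12 / 19)
  expect_equal(p$alpha, 13)
  expect_equal(p$beta, 8)
  expect_equal(p$bci_lo, qbeta(0.025, 13, 8))
  expect_equal(p$bci_hi, qbeta(0.975, 13, 8))
  expect_error(beta_posterior(5, 4), "0 <= k <= n")
})

test_that("Monte Carlo group comparison matches the quadrature oracle", {
  # identical posteriors are exchangeable
  p55 <- beta_posterior(5, 10)
  expect_lt(abs(compare_groups(p55, beta_posterior(5, 10), seed = 1) - 0.5),
            0.005)

  # well-separated groups
  expect_gt(compare_groups(beta_posterior(10, 10), beta_posterior(0, 10),
                           seed = 1), 0.99)

  # quadrature cross-checks
  pa <- beta_posterior(9, 10)
  pb <- beta_posterior(1, 10)
  oracle <- beta_gt_oracle(pa$alpha, pa$beta, pb$alpha, pb$beta)
  expect_lt(abs(compare_groups(pa, pb, seed = 2) - oracle), 0.005)

  # complement invariant: swapped arguments reuse the same draws
  got <- compare_groups(pa, pb, seed = 3)
  expect_equal(got + compare_groups(pb, pa, seed = 3), 1)

  expect_warning(compare_groups(pa, pb, n_draws = 500, seed = 1), "draws")
})

test_that("MC comparison agrees with quadrature over random group counts", {
  set.seed(19)
  for (i in 1:20) {
    n1 <- sample(3:25, 1); k1 <- sample(0:n1, 1)
    n2 <- sample(3:25, 1); k2 <- sample(0:n2, 1)
    pa <- beta_posterior(k1, n1)
    pb <- beta_posterior(k2, n2)
    est <- compare_groups(pa, pb, n_draws = 100000, seed = i)
    oracle <- beta_gt_oracle(pa$alpha, pa$beta, pb$alpha, pb$beta)
    se <- sqrt(oracle * (1 - oracle) / 100000)
    expect_lt(abs(est - oracle), 3 * se + 1e-4)
  }
})
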