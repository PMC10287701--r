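test_that("shuffle test detects a strong coherent signal and is reproducible", {
  set.seed(41)
  det <- sine_cohort(12, 4.6, ptp = 0.2, noise_sd = 0.02)
  r1 <- shuffle_null_test(det, n_perm = 200, seed = 7)
  expect_lt(r1$p, 0.05)
  expect_lt(abs(r1$peak$freq_hz - 4.6), 0.2 + 1e-9)
  r2 <- shuffle_null_test(det, n_perm = 200, seed = 7)
  expect_identical(r1$max_stat, r2$max_stat)
  expect_identical(r1$p, r2$p)
  # plus-one smoothing keeps p in (0, 1]
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  expect_error(shuffle_null_test(det, n_perm = 50), ">= 100")
  expect_error(shuffle_null_test(det[1], n_perm = 200), "2 participants")
})

test_that("AR(1) conditional least squares is consistent", {
  set.seed(42)
  # long series with known phi
  x <- as.numeric(arima.sim(list(ar = 0.5), n = 1e4, sd = 1))
  dc <- det_course(seq(0, by = 100 / 3, length.out = 1e4), x)
  fit <- fit_ar1(dc)
  expect_lt(abs(fit$phi - 0.5), 0.05)
  expect_lt(abs(fit$sigma_eps - 1), 0.05)
  # white noise: phi near zero
  w <- det_course(default_soa, rnorm(20))
  expect_lt(abs(fit_ar1(w)$phi), 2 / sqrt(20) + 0.2)
  # constant series: flagged degenerate
  dg <- fit_ar1(det_course(default_soa, rep(0.1, 20)))
  expect_true(dg$degenerate)
  expect_equal(dg$phi, 0)
  expect_equal(dg$sigma_eps, 0)
})

test_that("AR(1) surrogates reproduce the fitted autocorrelation", {
  set.seed(43)
  # long surrogates: the CLS refit is consistent, so the refitted phi must
  # recover the generating (fitted) phi
  x_long <- as.numeric(arima.sim(list(ar = 0.6), n = 5000, sd = 0.05))
  dc_long <- det_course(seq(0, by = 100 / 3, length.out = 5000), x_long)
  fit <- fit_ar1(dc_long)
  surr <- ar1_surrogate_courses(dc_long, 20, seed = 9)
  phis <- sapply(surr, function(s) fit_ar1(s)$phi)
  expect_lt(abs(mean(phis) - fit$phi), 0.05)
  # short (N = 20) surrogates: refitted phi matches fresh same-length draws
  # from the fitted model (both carry the same small-sample CLS bias)
  x20 <- as.numeric(arima.sim(list(ar = 0.6), n = 20, sd = 0.05))
  dc20 <- det_course(default_soa, x20)
  f20 <- fit_ar1(dc20)
  surr20 <- ar1_surrogate_courses(dc20, 1000, seed = 10)
  mean_surr <- mean(sapply(surr20, function(s) fit_ar1(s)$phi))
  ref <- mean(replicate(1000, {
    fit_ar1(det_course(default_soa,
                       f20$c_ar / (1 - f20$phi) +
                         as.numeric(arima.sim(list(ar = f20$phi), n = 20,
                                              sd = f20$sigma_eps))))$phi
  }))
  expect_lt(abs(mean_surr - ref), 0.1)
})

test_that("surrogate test is seed-reproducible and rejects non-stationary fits", {
  set.seed(44)
  det <- sine_cohort(8, 4.6, ptp = 0.15, noise_sd = 0.02)
  r1 <- ar1_surrogate_test(det, n_surr = 200, seed = 11)
  r2 <- ar1_surrogate_test(det, n_surr = 200, seed = 11)
  expect_identical(r1$max_stat, r2$max_stat)
  expect_lt(r1$p, 0.05)
})

test_that("Rayleigh statistics take their closed-form values", {
  r <- rayleigh_test(rep(1.3, 10))
  expect_equal(r$r, 1)
  expect_equal(r$z, 10)
  even <- rayleigh_test(seq(0, 2 * pi, length.out = 9)[-9])
  expect_lt(even$r, 1e-12)
  expect_lt(even$z, 1e-12)
  expect_equal(even$p, 1, tolerance = 1e-6)
  expect_error(rayleigh_test(1), "at least 2")
  expect_error(rayleigh_test(c(1, NaN)), "finite")
})

test_that("Rayleigh p-values are uniform under the circular-uniform null", {
  set.seed(45)
  p <- replicate(1e4, rayleigh_test(runif(55, 0, 2 * pi))$p)
  d <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(unname(d), 0.02)
})

test_that("bootstrap comparison: zero for identical cohorts, antisymmetric, detects 10 vs 5 Hz", {
  set.seed(46)
  a <- sine_cohort(10, 5, ptp = 0.15, noise_sd = 0.03)
  cmp_same <- bootstrap_peak_comparison(a, a, n_boot = 200, seed = 13)
  expect_equal(cmp_same$z, 0)
  expect_false(cmp_same$significant)
  b10 <- sine_cohort(10, 10, ptp = 0.15, noise_sd = 0.03)
  cmp <- bootstrap_peak_comparison(b10, a, n_boot = 200, seed = 13)
  expect_gt(cmp$z, 1.64)
  expect_true(cmp$significant)
  # swapping cohorts negates z exactly under the same seed
  cmp_sw <- bootstrap_peak_comparison(a, b10, n_boot = 200, seed = 13)
  expect_equal(cmp_sw$z, -cmp$z)
  # distributions reproduce under the seed
  cmp2 <- bootstrap_peak_comparison(b10, a, n_boot = 200, seed = 13)
  expect_identical(cmp$boot_freqs_a, cmp2$boot_freqs_a)
})

test_that("TOST declares equivalence correctly in the clear-cut cases", {
  set.seed(47)
  a <- sine_cohort(10, 5, ptp = 0.15, noise_sd = 0.03)
  a2 <- sine_cohort(10, 5, ptp = 0.15, noise_sd = 0.03)
  same <- tost_equivalence(bootstrap_peak_comparison(a, a2, n_boot = 200,
                                                     seed = 15))
  expect_true(same$equivalent)
  b7 <- sine_cohort(10, 7, ptp = 0.2, noise_sd = 0.02)
  diff2 <- tost_equivalence(bootstrap_peak_comparison(a, b7, n_boot = 200,
                                                      seed = 15))
  expect_false(diff2$equivalent)
})

test_that("ITC is 1 for identical phases and rotation-invariant", {
  expect_equal(rayleigh_test(rep(0.7, 8))$r, 1)
  set.seed(48)
  ph <- runif(30, -pi, pi)
  r1 <- rayleigh_test(ph)$r
  r2 <- rayleigh_test(ph + 1.234)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("paired one-sided t handles standard and degenerate inputs", {
  a <- c(0.7, 0.8, 0.75, 0.72)
  r0 <- paired_one_sided_t(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  r1 <- paired_one_sided_t(a + 1, a)
  expect_true(r1$degenerate)
  expect_lt(r1$p, 0.001)
  expect_error(paired_one_sided_t(a, a[1:2]), "equal length")
  # calibration: strong shift detected, null at alpha
  set.seed(49)
  rej_shift <- mean(replicate(100, {
    b <- rnorm(55, 0.65, 0.05)
    paired_one_sided_t(b + 0.1 + rnorm(55, 0, 0.05), b)$p < 0.05
  }))
  rej_null <- mean(replicate(200, {
    b <- rnorm(55, 0.65, 0.05)
    paired_one_sided_t(b + rnorm(55, 0, 0.05), b)$p < 0.05
  }))
  expect_gt(rej_shift, 0.99)
  expect_lt(abs(rej_null - 0.05), 0.05)
})

test_that("PLD permutation test is null-calibrated for identical conditions", {
  d <- rsvp_design(identities_per_condition = 6)
  g <- generative_params(osc_ptp = 0.12, phase_jitter_sd_rad = 0.2)
  tt <- simulate_cohort(d, g, 6, seed = 51)
  res <- itc_pld_test(tt, 4.6, n_perm = 100, seed = 52)
  expect_gt(res$p, 0.05)
  expect_lt(abs(res$pld), 0.5)
  expect_gte(res$itc_a, 0); expect_lte(res$itc_a, 1)
  expect_error(itc_pld_test(tt, 4.633, n_perm = 100), "frequency grid")
})

test_that("bootstrap power analysis: deterministic single draw, monotone signal", {
  set.seed(53)
  det <- sine_cohort(12, 4.6, ptp = 0.18, noise_sd = 0.03)
  p1 <- power_by_bootstrap(det, 8, n_boot = 1, n_perm = 100, seed = 55)
  p2 <- power_by_bootstrap(det, 8, n_boot = 1, n_perm = 100, seed = 55)
  expect_identical(p1, p2)
  pw <- power_by_bootstrap(det, c(3, 10), n_boot = 10, n_perm = 100,
                           seed = 56)
  expect_gte(pw$power[2] + 0.2, pw$power[1])  # non-decreasing within MC error
  expect_gt(pw$power[2], 0.7)
})
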