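test_that("aggregation reproduces hand counts", {
  tt <- data.frame(
    participant_id = "P1", condition = "a", n_targets = 2L,
    soa_ms = rep(c(200, 300), each = 4),
    identity_id = 1L,
    correct = c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 0L)
  )
  cs <- aggregate_accuracy(tt)
  expect_equal(cs[["P1"]]$accuracy, c(1, 0.5))
  expect_equal(cs[["P1"]]$n_trials, c(4L, 4L))
  # one-target scalar accuracies
  one_t <- data.frame(participant_id = c("P1", "P1", "P2", "P2"),
                   condition = "a", n_targets = 1L, soa_ms = NA_real_,
                   identity_id = 1L, correct = c(1L, 0L, 1L, 1L))
  expect_equal(as.numeric(aggregate_accuracy(one_t, n_targets_filter = 1)),
               c(0.5, 1))
})

test_that("an empty cell is rejected naming participant and SOA", {
  tt <- data.frame(participant_id = c("P1", "P1", "P2"), condition = "a",
                   n_targets = 2L, soa_ms = c(200, 300, 200),
                   identity_id = 1L, correct = 1L)
  expect_error(aggregate_accuracy(tt), "P2.*300")
})

test_that("cohort accuracies match generative rates within binomial CI", {
  d <- rsvp_design(conditions = "a", identities_per_condition = 5000,
                   reps_per_identity = 2, n_one_target = 0)
  g <- generative_params(osc_ptp = 0.1, phase_jitter_sd_rad = 0)
  tt <- simulate_cohort(d, g, 1, seed = 21)
  cr <- aggregate_accuracy(tt)[[1]]
  soa <- d$soa_levels_ms
  p_true <- g$trend_a0 * exp(-soa / g$trend_tau_ms) + g$trend_c +
    (g$osc_ptp / 2) * sin(2 * pi * g$osc_freq_hz * soa / 1000)
  expect_true(all(abs(cr$accuracy - p_true) <
                    qnorm(1 - 0.001 / 20) *
                      sqrt(p_true * (1 - p_true) / cr$n_trials)))
})

test_that("exponential parameters are recovered exactly on model data", {
  soa <- default_soa
  cr <- acc_course(soa, 0.2 * exp(-soa / 150) + 0.65)
  fit <- fit_exponential_trend(cr)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.2, 150, 0.65), tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
})

test_that("a constant course yields c = level and a0 = 0", {
  fit <- fit_exponential_trend(acc_course(default_soa, rep(0.7, 20)))
  expect_equal(fit$c, 0.7, tolerance = 1e-6)
  expect_equal(fit$a0, 0, tolerance = 1e-6)
})

test_that("a vertical shift of model data moves only the asymptote", {
  soa <- default_soa
  f1 <- fit_exponential_trend(acc_course(soa, 0.15 * exp(-soa / 200) + 0.6))
  f2 <- fit_exponential_trend(acc_course(soa, 0.15 * exp(-soa / 200) + 0.65))
  expect_equal(f2$c - f1$c, 0.05, tolerance = 1e-5)
  expect_equal(f2$a0, f1$a0, tolerance = 1e-5)
  expect_equal(f2$tau_ms, f1$tau_ms, tolerance = 1e-2)
})

test_that("fewer than 4 points is rejected", {
  expect_error(fit_exponential_trend(acc_course(c(200, 233, 267), rep(0.7, 3))),
               "at least 4")
})

test_that("detrending removes the trend and recovers an injected sinusoid", {
  soa <- default_soa
  trend <- 0.1 * exp(-soa / 300) + 0.7
  # 7.5 Hz = 5 full cycles over the 667 ms window, so the sinusoid has no
  # trend-like leakage for the exponential to absorb
  osc <- 0.05 * sin(2 * pi * 7.5 * soa / 1000)
  cr <- acc_course(soa, trend + osc)
  fit <- fit_exponential_trend(cr)
  dc <- detrend(cr, fit)
  expect_gt(cor(dc$residual, osc), 0.99)
  # at a frequency with partial-cycle leakage (4.6 Hz here) the exponential
  # legitimately absorbs a little of the sinusoid; recovery is still strong
  osc2 <- 0.05 * sin(2 * pi * 4.6 * soa / 1000)
  cr2 <- acc_course(soa, trend + osc2)
  dc2 <- detrend(cr2, fit_exponential_trend(cr2))
  expect_gt(cor(dc2$residual, osc2), 0.95)
  # a course equal to its own fitted trend detrends to zero
  cr2 <- acc_course(soa, fit$fitted)
  expect_equal(detrend(cr2, fit)$residual, rep(0, 20), tolerance = 1e-12)
})

test_that("detrending is idempotent up to fit noise", {
  soa <- default_soa
  cr <- acc_course(soa, 0.12 * exp(-soa / 250) + 0.68 +
                     0.04 * sin(2 * pi * 5 * soa / 1000))
  dc <- detrend(cr, fit_exponential_trend(cr))
  refit <- fit_exponential_trend(acc_course(soa, dc$residual + 0.5))
  expect_lt(abs(refit$a0), 0.02)
})

test_that("grid mismatch between course and trend is rejected", {
  cr <- acc_course(default_soa, rep(0.7, 20))
  fit <- fit_exponential_trend(cr)
  cr_shift <- acc_course(default_soa + 33.3, rep(0.7, 20))
  expect_error(detrend(cr_shift, fit), "different SOA grid")
})

test_that("fitted SSE never exceeds the nested constant model's", {
  set.seed(99)
  soa <- default_soa
  for (i in 1:20) {
    y <- pmin(pmax(runif(1, 0.4, 0.9) + rnorm(20, 0, 0.1), 0), 1)
    cr <- acc_course(soa, y)
    fit <- fit_exponential_trend(cr)
    expect_lte(fit$sse, sum((y - mean(y))^2) + 1e-10)
  }
})

test_that("residual means on a synthetic cohort are near zero", {
  d <- rsvp_design(identities_per_condition = 6)
  tt <- simulate_cohort(d, generative_params(), 6, seed = 23)
  det <- detrend_cohort(aggregate_accuracy(tt))
  fits <- attr(det, "trend_fits")
  for (i in seq_along(det)) {
    if (fits[[i]]$converged) {
      expect_lte(abs(mean(det[[i]]$residual)), 0.02)
    }
  }
})
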