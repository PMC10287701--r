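test_that("spectrum matches the naive double-loop DFT oracle", {
  set.seed(31)
  for (i in 1:5) {
    y <- rnorm(20, 0, 0.05)
    dc <- det_course(default_soa, y)
    sp <- compute_spectrum(dc, spectral_config())
    X <- naive_dft(y, 300)
    expect_lt(max(Mod(sp$coeff - X)), 1e-10)
    expect_equal(sp$amplitude, 2 * Mod(X) / 300, tolerance = 1e-12)
    # compare phases on the circle (+pi and -pi are the same angle)
    expect_lt(max(abs(Arg(exp(1i * (sp$phase - Arg(X)))))), 1e-10)
  }
})

test_that("calibration sinusoid reproduces the 0.0167 a.u. peak amplitude", {
  sp <- compute_spectrum(make_calibration_course(4.6, 0.5), spectral_config())
  amp <- sp$amplitude[which(abs(sp$freqs_hz - 4.6) < 1e-9)]
  expect_equal(amp, 0.0167, tolerance = 0.05)
})

test_that("all-zero input gives all-zero amplitudes", {
  sp <- compute_spectrum(det_course(default_soa, rep(0, 20)))
  expect_equal(sp$amplitude, rep(0, length(sp$freqs_hz)))
})

test_that("unequal spacing is rejected", {
  soa <- default_soa
  soa[5] <- soa[5] + 1
  expect_error(compute_spectrum(det_course(soa, rnorm(20))), "equally spaced")
})

test_that("zero padding samples the same DTFT: M = 300 vs M = 600 agree", {
  set.seed(32)
  y <- rnorm(20, 0, 0.05)
  s300 <- compute_spectrum(det_course(default_soa, y),
                           spectral_config(freq_resolution_hz = 0.1))
  s600 <- compute_spectrum(det_course(default_soa, y),
                           spectral_config(freq_resolution_hz = 0.05))
  common <- match(round(s300$freqs_hz, 6), round(s600$freqs_hz, 6))
  # same DTFT samples once the 1/M normalization is undone
  expect_lt(max(abs(s300$amplitude * 300 - s600$amplitude[common] * 600)),
            1e-10)
})

test_that("the unpadded transform conserves energy (Parseval)", {
  set.seed(33)
  y <- rnorm(16)
  X <- fft(y)
  expect_equal(sum(y^2), sum(Mod(X)^2) / length(y), tolerance = 1e-10)
  # and the padded transform's coefficients equal the oracle on random input
  Xo <- naive_dft(y, 32)
  expect_lt(max(Mod(fft(c(y, rep(0, 16)))[1:17] - Xo)), 1e-10)
})

test_that("phase-locked sum matches brute-force complex averaging", {
  set.seed(34)
  spectra <- lapply(1:7, function(k) {
    compute_spectrum(det_course(default_soa, rnorm(20, 0, 0.05),
                                participant_id = sprintf("P%d", k)))
  })
  pls <- phase_locked_sum(spectra)
  brute <- sapply(seq_along(pls$freqs_hz), function(i) {
    acc <- 0 + 0i
    for (s in spectra) acc <- acc + s$amplitude[i] * exp(1i * s$phase[i])
    Mod(acc / length(spectra))
  })
  expect_lt(max(abs(pls$pls - brute)), 1e-12)
})

test_that("PLS of identical spectra equals the individual amplitude", {
  sp <- compute_spectrum(sine_course(5, 0.2))
  pls <- phase_locked_sum(list(sp, sp, sp))
  expect_equal(pls$pls, sp$amplitude, tolerance = 1e-12)
  expect_equal(phase_locked_sum(list(sp))$pls, sp$amplitude,
               tolerance = 1e-15)
})

test_that("evenly spaced phases cancel to a zero PLS", {
  base <- compute_spectrum(sine_course(5, 0.2))
  n <- 4
  spectra <- lapply(0:(n - 1), function(k) {
    s <- base
    s$phase <- s$phase + 2 * pi * k / n
    s
  })
  expect_lt(max(phase_locked_sum(spectra)$pls), 1e-12)
})

test_that("PLS never exceeds the mean individual amplitude", {
  set.seed(35)
  spectra <- lapply(1:6, function(k) {
    compute_spectrum(det_course(default_soa, rnorm(20, 0, 0.05)))
  })
  pls <- phase_locked_sum(spectra)
  mean_amp <- rowMeans(sapply(spectra, `[[`, "amplitude"))
  expect_true(all(pls$pls <= mean_amp + 1e-12))
})

test_that("find_peak locates peaks, breaks ties low and flags edges", {
  sp <- compute_spectrum(sine_course(5, 0.2))
  expect_equal(find_peak(sp, c(3, 13))$freq_hz, 5)
  flat <- structure(list(freqs_hz = seq(0, 15, 0.1),
                         pls = rep(1, 151), n = 1L), class = "pls_curve")
  pk <- find_peak(flat, c(3, 13))
  expect_equal(pk$freq_hz, 3)
  expect_true(pk$edge)
  expect_error(find_peak(sp, c(13.01, 13.02)), "no frequency bins")
})

test_that("amplitude-to-range conversion inverts the padding loss", {
  expect_equal(amplitude_to_variance(0.0167, 20, 300), 0.501)
  expect_equal(amplitude_to_variance(0, 20, 300), 0)
  expect_error(amplitude_to_variance(0.1, 20, 10), ">=")
  # round trip through the spectrum for several frequencies and ranges
  for (f in c(3.5, 4.6, 7.7, 10.2)) {
    for (ptp in c(0.1, 0.5)) {
      sp <- compute_spectrum(make_calibration_course(f, ptp))
      pk <- find_peak(sp, c(3, 13))
      rec <- amplitude_to_variance(pk$value, sp$n_samples, sp$n_padded)
      expect_lt(abs(rec - ptp) / ptp, 0.10)  # leakage tolerance
    }
  }
})
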