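# hand-built course objects so tests do not depend on internal constructors

acc_course <- function(soa_ms, accuracy, n_trials = rep(48L, length(soa_ms)),
                       participant_id = "P1", condition = "all") {
  structure(list(participant_id = participant_id, condition = condition,
                 soa_ms = soa_ms, accuracy = accuracy, n_trials = n_trials),
            class = "accuracy_course")
}

det_course <- function(soa_ms, residual, participant_id = "P1",
                       condition = "all") {
  structure(list(participant_id = participant_id, condition = condition,
                 soa_ms = soa_ms, residual = residual),
            class = "detrended_course")
}

default_soa <- rsvp_design()$soa_levels_ms

# noiseless sinusoidal detrended course on the default grid
sine_course <- function(freq_hz, ptp = 0.1, phase = 0, soa = default_soa,
                        participant_id = "P1") {
  det_course(soa, (ptp / 2) * sin(2 * pi * freq_hz * soa / 1000 + phase),
             participant_id = participant_id)
}

# cohort of noisy sinusoidal detrended courses (shared phase -> coherent)
sine_cohort <- function(n, freq_hz, ptp = 0.1, noise_sd = 0.02, phase = 0,
                        soa = default_soa) {
  lapply(seq_len(n), function(k) {
    det_course(soa,
               (ptp / 2) * sin(2 * pi * freq_hz * soa / 1000 + phase) +
                 rnorm(length(soa), 0, noise_sd),
               participant_id = sprintf("P%03d", k))
  })
}

# naive O(N*M) DFT oracle: X_j = sum_t y_t exp(-2 pi i j t / M), zero padded
naive_dft <- function(y, M) {
  N <- length(y)
  X <- complex(M %/% 2 + 1)
  for (j in 0:(M %/% 2)) {
    acc <- 0 + 0i
    for (t in 0:(N - 1)) {
      acc <- acc + y[t + 1] * exp(-2i * pi * j * t / M)
    }
    X[j + 1] <- acc
  }
  X
}
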