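Package: behavosc
Title: Behavioral Oscillation Analysis for Dense-Sampling RSVP Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Detects and characterises rhythmic fluctuations of perceptual
    accuracy in dual-target rapid serial visual presentation (RSVP)
    experiments that sample performance densely over stimulus onset
    asynchrony (SOA). Provides exponential-decay detrending of
    per-participant accuracy time courses, zero-padded FFT spectra with a
    fixed amplitude normalisation, the group phase-locked sum (PLS)
    statistic, SOA-shuffle permutation and AR(1)-surrogate null
    distributions with maximum-statistic multiple-comparison correction,
    Rayleigh tests and inter-trial phase coherence contrasts, bootstrap
    peak-frequency comparison with two one-sided equivalence testing,
    complementary sinusoidal fitting with a sliding-window fit-decay
    analysis, a bootstrap power analysis, and a synthetic trial-level
    cohort generator with known ground-truth oscillatory structure for
    end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
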