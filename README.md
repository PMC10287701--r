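# behavosc

Analysis of **behavioral oscillations** in dense-sampling dual-target RSVP
(rapid serial visual presentation) psychophysics, for researchers studying
rhythmic attentional sampling. In this paradigm two identical face targets
are embedded in a 30 Hz stream of object distractors, separated by a
stimulus onset asynchrony (SOA) spanning 20 levels from 200 to 833 ms in
33.3 ms steps; discrimination accuracy as a function of SOA is a 20-point
time course sampled at an effective 30 Hz. If the first target resets an
ongoing perceptual rhythm, accuracy oscillates over SOA coherently across
participants.

The core statistic is the group **phase-locked sum**. After removing each
participant's exponential trend, `f(x) = a0 exp(-x/tau) + c`, the
residuals are zero-padded to 0.1 Hz resolution and Fourier transformed
(amplitude convention `A = 2|X|/M`), and

```
PLS_f = | (1/n) * sum_k A_(f,k) exp(i theta_(f,k)) |
```

is large only when the individual spectra agree in phase across
participants. Significance comes from two complementary nulls — SOA-shuffle
permutation and AR(1)-surrogate series — both corrected over frequencies by
the maximum statistic, plus a Rayleigh test of phase concentration at the
peak. A time-domain sinusoidal fit (with permutation p-value and a 233 ms
sliding-window fit-decay analysis), bootstrap peak-frequency comparison
between conditions with TOST equivalence testing, an inter-trial
phase-coherence contrast (PLD), and a bootstrap power analysis complete the
pipeline. A synthetic trial-level cohort generator with known ground truth
makes every stage verifiable end to end.

## Worked example

Simulate a phase-coherent cohort oscillating at 4.6 Hz and run the full
pipeline at desk-scale iteration counts:

```r
library(behavosc)

design <- rsvp_design()                     # 20 SOAs, 1008 trials/participant
gen    <- generative_params(osc_ptp = 0.15, phase_jitter_sd_rad = 0)
trials <- simulate_cohort(design, gen, n_participants = 12, seed = 11)

report <- run_full_analysis(trials, analysis_config("ci", seed = 5), design)
report
```

```
==== Behavioral-oscillation study report ====
12 participants, 20 SOA levels, seed 5 (ci profile)

Accuracy: familiar 71.09% vs unfamiliar 71.35%; one-sided paired t(11) = -0.41, p = 0.654

-- Combined conditions --
SOA-shuffle permutation test of the phase-locked sum (500 iterations)
  band 3-13 Hz; peak 0.004719 at 4.50 Hz
  corrected p = 0.001996
  AR(1)-surrogate corrected p = 0.001996
Rayleigh test: n = 12, R = 0.951, z = 10.853, p = 3.739e-07
  peak-to-peak modulation explained: 14.86%
Sinusoidal fit: 4.52 Hz, amplitude 0.07077, adj R^2 = 0.875, permutation p = 0.001996

Bootstrap peak-frequency comparison (200 resamples, band 3-13 Hz)
  mean peak A 4.61 Hz (SE 0.087) vs B 4.46 Hz (SE 0.061)
  z = 1.342 (one-sided critical 1.64): no detected difference
TOST equivalence (margin 0.50 Hz, alpha 0.05): diff 0.143 Hz -> EQUIVALENT
Phase-locking difference at 4.50 Hz (500 permutations)
  ITC(familiar) = 0.939, ITC(unfamiliar) = 0.901, PLD = 0.0372, one-sided p = 0.2994
```

(abridged; the full report also prints the per-condition spectra and the
sliding-window fit decay). Reading the key numbers: the group PLS peaks
within one 0.1 Hz bin of the injected 4.6 Hz and beats both the shuffle
and the AR(1)-surrogate nulls at their p-value floor `1/(n_iter+1)`; the
Rayleigh resultant length R = 0.95 confirms the phases are tightly
aligned across participants (the cohort was generated with zero phase
jitter); the recovered peak-to-peak modulation, 14.9%, matches the
injected `osc_ptp = 0.15`; and the two (identically generated) conditions
are declared equivalent in peak frequency by the TOST procedure while the
PLD contrast is correctly null.

The amplitude calibration that anchors the effect-size conversion:

```r
sp <- compute_spectrum(make_calibration_course(freq_hz = 4.6, ptp = 0.5))
sp$amplitude[sp$freqs_hz == 4.6]      # 0.01666 a.u.
amplitude_to_variance(1, 20, 300)     # 30: amplitude -> peak-to-peak range
```

A noiseless 4.6 Hz sinusoid swinging -25% to +25% yields a spectral peak
of 0.0167 a.u. under the pipeline's normalisation — zero-padding a
20-sample course to 300 spreads its energy, and the factor `2M/N = 30`
inverts that loss.

A thin command-line wrapper with `simulate`, `analyze`, `power` and
`calibrate` verbs lives at `inst/scripts/behavosc-cli.R`.

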