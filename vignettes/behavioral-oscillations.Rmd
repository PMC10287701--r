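---
title: "Detecting behavioral oscillations in dense-sampling RSVP data"
author: "behavosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting behavioral oscillations in dense-sampling RSVP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavosc)
```

## The problem

Perceptual performance is not constant in time: accuracy in many detection
and discrimination tasks waxes and wanes rhythmically, typically in the
theta (3–7 Hz) and alpha (8–12 Hz) bands, reflecting periodic attentional
sampling. The dense-sampling dual-target RSVP paradigm measures this
behaviorally: two identical face targets are embedded in a 30 Hz stream of
object distractors, separated by a stimulus onset asynchrony (SOA) that
varies over 20 levels from 200 to 833 ms in one-frame (33.3 ms) steps, and
the participant reports the target's gender. Accuracy as a function of SOA
is then a 20-point time course sampled at an effective 30 Hz; if the first
target resets an ongoing perceptual rhythm, accuracy oscillates over SOA
coherently across participants.

`behavosc` implements the complete analysis chain for such data — trend
removal, spectral statistics, permutation and surrogate inference, circular
statistics, sinusoidal fitting, and condition comparisons — together with a
synthetic trial-level generator with known ground truth, so that every
stage can be verified end to end without access to any particular dataset.

## The generative model behind the synthetic cohorts

`simulate_cohort()` draws Bernoulli trial outcomes from

$$p_k(x) \;=\; \mathrm{clamp}\!\left[\,a_0 e^{-x/\tau} + c
  + \tfrac{\mathrm{ptp}}{2}\,
  \sin\!\big(2\pi f x/1000 + \phi + \delta_k\big),\; 0,\; 1\right],$$

where $x$ is the SOA in ms, $a_0 e^{-x/\tau} + c$ is a slowly decaying
trend (targets within one processing cycle tend to be integrated, so
accuracy starts slightly elevated), and the sinusoid is the behavioral
oscillation. $\delta_k \sim N(0, \sigma_\phi^2)$ is a *single*
per-participant phase offset: it is deliberately not redrawn per trial,
because it is precisely the cross-participant phase coherence that the
phase-locked sum, Rayleigh and ITC stages measure, and a per-trial jitter
would conflate phase coherence with trial noise.

Default parameters, chosen once as a realistic cohort: $a_0 = 0.08$,
$\tau = 250$ ms, $c = 0.70$ (dual-target accuracy in the low 70s%),
$f = 4.6$ Hz with peak-to-peak range 0.044 (the effect size such studies
report), phase 0 at first-target onset, phase jitter SD 0.5 rad, and
one-target accuracy 0.686. Time zero for the oscillation is first-target
onset, the phase-reset event, so the sinusoid is evaluated at $t =$ SOA.
Clamping into $[0,1]$ happens after summing trend and oscillation; clamp
events are counted and a warning is raised when more than 5% of rate
evaluations clamp, since silent clamping distorts the injected amplitude.

What the generator does *not* emulate: response-time structure, lapses,
learning or fatigue across blocks, and any non-sinusoidal (e.g. bursty)
rhythmicity. Passing tests therefore show that the pipeline recovers what
it assumes — a phase-reset sinusoid on an exponential trend with binomial
noise — not that real data satisfy those assumptions.

## Detrending

The accuracy course of each participant is fitted with
$f(x) = a_0 e^{-x/\tau} + c$ and the fit is subtracted; no smoothing or
filtering is applied. The exponential has a notoriously flat likelihood in
$\tau$ when $a_0$ is small, so the bounded least-squares problem
($a_0 \in [-1, 1]$, $\tau \in [10, 10^4]$ ms, $c \in [0, 1]$; bounds keep
the curve in accuracy units and the exponent finite) is solved by
multi-start L-BFGS-B from six initialisations
($a_0 \in \{y_1 - y_N,\, 0\}$, $\tau \in \{100, 300, 1000\}$ ms,
$c = y_N$), keeping the lowest-SSE solution. A gradient-based bounded
optimiser was preferred over a Gauss–Newton NLS routine because the fit
sits inside resampling loops (thousands of refits in the label-permutation
test) and must never error on degenerate inputs; when no start improves on
the nested constant model ($a_0 = 0$, $c = \bar y$), the constant model is
returned with `converged = FALSE`, which also guarantees the invariant
that the fitted SSE never exceeds the constant model's.

## Spectra, the phase-locked sum, and the amplitude convention

Each detrended course (N = 20 points at 30 Hz) is zero-padded to
M = 300 samples, giving 0.1 Hz bins, and Fourier transformed; no window is
applied. Amplitudes are normalised as $A = 2|X|/M$ uniformly across bins.
This convention is the one under which a noiseless sinusoid of
peak-to-peak range 0.5 at 4.6 Hz on the default grid yields a peak of
0.0167 a.u.:

```{r}
sp <- compute_spectrum(make_calibration_course(4.6, 0.5))
sp$amplitude[sp$freqs_hz == 4.6]
```

Zero padding refines the frequency grid but spreads the N-sample signal's
energy over M bins, so the half-amplitude 0.25 appears as
$0.25 \cdot N/M = 0.0167$; the inverse factor $2M/N = 30$
(`amplitude_to_variance()`) converts a measured peak back into the
peak-to-peak modulation range ("variance" in the field's loose usage: a
range of 0.5 means −25% to +25% around trend).

The group statistic is the phase-locked sum

$$\mathrm{PLS}_f = \Big|\tfrac{1}{n}\sum_k A_{f,k}\, e^{i\theta_{f,k}}\Big|,$$

the modulus of the across-participant mean of the normalised complex
spectra. It is numerically identical to averaging the raw complex FFT
coefficients (scaled by $2/M$): the exponent is $e^{i\theta}$ with
$\theta$ the FFT phase angle in radians. Incoherent phases cancel, so the
PLS is large only for oscillations that are phase-aligned across
participants — the signature of a phase reset by the first target. Because
samples are indexed 0…N−1 from the first SOA, the absolute phase reference
is arbitrary, but it cancels in every comparison the pipeline makes
(phases are only compared across participants or conditions on the same
grid).

## Inference

**SOA-shuffle permutation.** Each iteration independently permutes every
participant's residuals across SOA positions and recomputes the full
spectra and PLS. Multiple comparisons over frequencies are corrected by
taking the maximum PLS across the tested band per iteration. P-values use
plus-one smoothing, $p = (1 + \#\{\max \ge \mathrm{obs}\})/(1 + B)$ — a
valid finite-sample p-value that can never be 0 — rather than a bare
95th-percentile exceedance; the per-frequency 95th-percentile curve is
still computed for plots.

**AR(1) surrogates.** Shuffling in time destroys aperiodic autocorrelation
along with any rhythm, which can make smooth non-oscillatory structure
look significant. The surrogate null therefore fits
$X_t = c + \phi X_{t-1} + \epsilon_t$ to each participant's residuals by
conditional least squares (simple, adequate at N = 20, and estimator
choice is otherwise unconstrained) and replaces each course with a fresh
AR(1) realization per iteration (100 burn-in steps discarded), preserving
lag-1 structure while carrying no oscillation. The same maximum-statistic
correction applies. A peak should beat both nulls.

**Circular statistics.** At the group peak, phase concentration across
participants is tested with the Rayleigh statistic $z = nR^2$ ($R$ the
mean resultant length) and the standard Zar approximation
$p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - (nR)^2)} - (1 + 2n)\big)$, which is
verified to produce uniform p-values under the circular-uniform null (KS
distance < 0.02 at $10^4$ simulations).

**Condition comparisons.** Peak frequencies of two conditions are compared
by resampling participants with replacement (the *same* draw applied to
both conditions — the design is within-subject, so resampling must respect
pairing), recording each condition's band peak, and standardising the mean
difference by the combined bootstrap SE; the one-sided critical value is
1.64. A non-significant difference is followed by a two one-sided tests
(TOST) equivalence procedure with margin 0.5 Hz at $\alpha = 0.05$, and by
a paired one-sided t-test on the per-participant modulation ranges at the
peak. The phase-locking difference
$\mathrm{PLD} = \mathrm{ITC}_a - \mathrm{ITC}_b$ is tested by permuting
condition labels across trials *within* each participant (participants
are not exchangeable units; trials within a participant are) and rerunning
the whole chain — aggregation, detrend, spectrum, phase — on every
permutation; permutations that would empty a (participant, condition, SOA)
cell are redrawn and counted. The default peak-search band for all of
these is the analysed 3–13 Hz band, switchable to the full 0–15 Hz range.

## Sinusoidal fitting and the sliding window

As a time-domain cross-check, the group-average residual course is fitted
at each frequency of a 0.01 Hz grid with
$a \sin(2\pi f t) + b \cos(2\pi f t) + d$ — linear in the coefficients,
hence convex and deterministic per frequency, with the 0.01 Hz grid
matching the two-decimal reporting convention for best-fit frequencies.
The best frequency maximises $R^2$ (ties break toward the lower
frequency); adjusted $R^2$ uses $p = 3$ coefficients; significance comes
from permuting the course over SOA positions and taking the maximum
adjusted $R^2$ per permutation.

The sliding-window analysis quantifies how the fit decays with distance
from the phase reset: the series is zero-padded by half a window at both
ends, and at each SOA centre a 233 ms (7-sample) window of the data is
compared with the corresponding segment of the *fixed* global best-fit
sinusoid — no per-window refit, so the question stays "does the data still
follow the one fitted rhythm here?". The goodness of fit is the squared
Pearson correlation between the two segments, which stays in $[0, 1]$
(one minus a residual ratio against a fixed curve can go negative and
would not be an $R^2$ in any bounded sense). The familywise threshold is
the 95th percentile, over AR(1) surrogate series, of each surrogate's
maximum windowed fit across centres.

## The orchestrated pipeline

`run_full_analysis()` chains every stage — accuracy summaries and the
one-sided paired t-test between conditions, detrending, spectra, PLS with
both corrected p-values for the combined data and per condition, Rayleigh
at the peak, sinusoid fit with permutation p and sliding window, bootstrap
frequency comparison with conditional TOST and amplitude t-test, and the
PLD test at the combined peak — into a `study_report` that reproduces
bit-identically from the same inputs and seed. For the combined analysis
the pooled accuracy courses are detrended directly (pooled-then-detrend);
averaging per-condition residuals instead is available via
`combined_detrend = "average"`, since with roughly balanced designs the
two differ only through the nonlinearity of the trend fit.

Iteration counts are profile-scaled: the `"full"` profile uses the
reference counts (10,000 permutations and surrogates, 1,000 bootstrap
resamples), the `"ci"` profile uses 500/500/200 for desk-scale runs. The
package's own verification suite runs at desk scale: type-I calibration
uses 200 no-signal cohorts of 12 participants (48 trials per SOA) at 500
iterations per test, and signal recovery uses 50 cohorts of 55
participants with a coherent 4.6 Hz, 0.15 peak-to-peak modulation. Trial
tables round-trip through a plain CSV with the documented header;
participants below 50% accuracy at the shortest (easiest) SOA are excluded
on read, with their ids recorded.

## Numerical choices and limitations

* Peak ties break toward the lower frequency, and peaks on a band edge
  are flagged — an edge peak suggests the true maximum lies outside the
  analysed band.
* Degenerate inputs are handled explicitly rather than by error: constant
  courses give a flagged constant-model trend fit and a flagged
  zero-variance AR(1) fit; zero-variance paired differences resolve the
  t-test by sign; a zero bootstrap SE resolves the z and TOST decisions
  analytically, flagged.
* All permutation p-values are plus-one smoothed and hence never exactly
  zero; with $B$ iterations the smallest attainable p is $1/(B+1)$.
* The spectral amplitude convention ties the printed calibration numbers
  together ($0.0167 \times 30 = 0.5$); any other normalisation would
  change both by the same factor and cancel in every ratio the pipeline
  reports.
* The two nulls are not interchangeable in their finite-sample behavior.
  Within the full pipeline the AR(1)-surrogate test tends toward the
  conservative side of nominal — detrending removes three degrees of
  freedom and slow spectral content from the observed residuals while
  surrogates carry a full AR spectrum — whereas applied to raw
  autocorrelated series without the detrending step it can run mildly
  liberal, because conditioning on AR parameters estimated from 20 points
  ignores their sampling uncertainty. Treat the surrogate p-value as the
  stricter of the two checks within the pipeline, not as an exactly
  nominal test.
* The exponential detrend can absorb a small part of a genuine
  oscillation whose partial cycles leak into trend-like components; the
  absorption vanishes for frequencies completing whole cycles over the
  sampled window and is a few percent of the amplitude otherwise.
* Detection power depends steeply on cross-participant phase coherence:
  with large phase jitter the PLS loses signal even when every individual
  oscillates strongly. That is by design — the statistic targets
  phase-reset rhythms — but it means a null result does not rule out
  incoherent oscillations.
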