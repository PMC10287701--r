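#' Generative parameters for a synthetic cohort
#'
#' Specifies the per-participant accuracy model used by [simulate_cohort()]:
#' an exponential decay over SOA plus a phase-coherent sinusoidal
#' modulation,
#' \deqn{p(x) = a_0 e^{-x/\tau} + c +
#'       \frac{ptp}{2}\sin(2\pi f x / 1000 + \phi + \delta_k),}
#' with `x` the SOA in ms and `delta_k ~ N(0, jitter^2)` a single
#' per-participant phase offset. Trial outcomes are Bernoulli draws from
#' `p(x)` clamped to `[0, 1]`.
#'
#' Defaults describe a realistic dual-target face-discrimination cohort:
#' baseline accuracy around 0.70 with a mild early integration benefit
#' (`a0 = 0.08`, `tau = 250` ms), a theta-band modulation at 4.6 Hz whose
#' peak-to-peak range of 0.044 matches the effect size such studies report,
#' moderate cross-participant phase jitter (0.5 rad), and one-target
#' baseline accuracy 0.686.
#'
#' @param trend_a0 Starting amplitude of the decay trend (accuracy units).
#' @param trend_tau_ms Decay time constant in ms (> 0).
#' @param trend_c Asymptotic accuracy in `[0, 1]`.
#' @param osc_freq_hz Oscillation frequency in Hz.
#' @param osc_ptp Peak-to-peak accuracy modulation in `[0, 1]`.
#' @param osc_phase_rad Oscillation phase in radians at the first target
#'   onset (t = 0); the sinusoid is evaluated at t = SOA.
#' @param phase_jitter_sd_rad SD of the per-participant phase offset
#'   (radians, >= 0). Zero gives a perfectly phase-coherent cohort.
#' @param one_target_acc Accuracy of one-target baseline trials.
#' @return An object of class `"generative_params"`.
#' @export
generative_params <- function(trend_a0 = 0.08,
                              trend_tau_ms = 250,
                              trend_c = 0.70,
                              osc_freq_hz = 4.6,
                              osc_ptp = 0.044,
                              osc_phase_rad = 0,
                              phase_jitter_sd_rad = 0.5,
                              one_target_acc = 0.686) {
  if (trend_tau_ms <= 0) stopf("trend_tau_ms must be positive")
  if (trend_c < 0 || trend_c > 1) stopf("trend_c must lie in [0, 1]")
  if (osc_ptp < 0 || osc_ptp > 1) stopf("osc_ptp must lie in [0, 1]")
  if (phase_jitter_sd_rad < 0) stopf("phase_jitter_sd_rad must be >= 0")
  if (one_target_acc < 0 || one_target_acc > 1) {
    stopf("one_target_acc must lie in [0, 1]")
  }
  structure(
    list(trend_a0 = trend_a0, trend_tau_ms = trend_tau_ms, trend_c = trend_c,
         osc_freq_hz = osc_freq_hz, osc_ptp = osc_ptp,
         osc_phase_rad = osc_phase_rad,
         phase_jitter_sd_rad = phase_jitter_sd_rad,
         one_target_acc = one_target_acc),
    class = "generative_params"
  )
}

# noiseless success probability curve for one participant
.true_rates <- function(gen, soa_ms, delta = 0) {
  gen$trend_a0 * exp(-soa_ms / gen$trend_tau_ms) + gen$trend_c +
    (gen$osc_ptp / 2) *
      sin(2 * pi * gen$osc_freq_hz * soa_ms / 1000 +
            gen$osc_phase_rad + delta)
}

#' Simulate a trial-level cohort with known oscillatory structure
#'
#' Generates a tidy trial table for `n_participants` following the design in
#' `design` and the generative model in `gen` (see [generative_params()]).
#' Each dual-target outcome is a Bernoulli draw from the participant's
#' clamped accuracy curve; one-target outcomes are Bernoulli draws at
#' `one_target_acc`. The same seed yields a bit-identical table.
#'
#' Pass a named list of `generative_params` (one per condition label) to
#' give conditions different oscillations or phase coherence; with a single
#' `generative_params` all conditions share one per-participant phase
#' offset.
#'
#' @param design An [rsvp_design()].
#' @param gen A [generative_params()] object, or a named list of them keyed
#'   by the design's condition labels.
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param max_clamp_frac If more than this fraction of evaluated rate points
#'   had to be clamped into `[0, 1]`, a warning is raised (the injected
#'   amplitude is being distorted). Default 0.05.
#' @return A `data.frame` of class `"trial_table"` with columns
#'   `participant_id`, `condition`, `n_targets`, `soa_ms` (`NA` for
#'   one-target trials), `identity_id`, `correct`, and an attribute
#'   `n_clamped` counting clamped rate evaluations.
#' @examples
#' d <- rsvp_design(identities_per_condition = 2, n_one_target = 4)
#' tt <- simulate_cohort(d, generative_params(), n_participants = 2, seed = 1)
#' nrow(tt) == 2 * d$n_trials_total
#' @export
simulate_cohort <- function(design, gen, n_participants, seed = NULL,
                            max_clamp_frac = 0.05) {
  stopifnot(inherits(design, "rsvp_design"))
  if (n_participants < 1) stopf("n_participants must be >= 1")
  conds <- design$conditions
  if (inherits(gen, "generative_params")) {
    gen_by_cond <- NULL
  } else if (is.list(gen) && all(conds %in% names(gen)) &&
             all(vapply(gen, inherits, TRUE, "generative_params"))) {
    gen_by_cond <- gen[conds]
  } else {
    stopf("gen must be a generative_params object or a named list of them covering all conditions")
  }

  soa <- design$soa_levels_ms
  n_soa <- length(soa)
  ids <- seq_len(design$identities_per_condition)
  reps <- seq_len(design$reps_per_identity)
  with_seed(seed, {
    n_clamped <- 0L
    n_rates <- 0L
    out <- vector("list", n_participants)
    for (k in seq_len(n_participants)) {
      pid <- sprintf("P%03d", k)
      # dual-target block: soa x condition x identity x repetition
      grid <- expand.grid(rep = reps, identity_id = ids, condition = conds,
                          soa_ms = soa, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      if (is.null(gen_by_cond)) {
        delta <- stats::rnorm(1L, 0, gen$phase_jitter_sd_rad)
        p_by <- lapply(conds, function(cc) .true_rates(gen, soa, delta))
        one_acc <- gen$one_target_acc
      } else {
        p_by <- lapply(conds, function(cc) {
          g <- gen_by_cond[[cc]]
          .true_rates(g, soa, stats::rnorm(1L, 0, g$phase_jitter_sd_rad))
        })
        one_acc <- mean(vapply(gen_by_cond, `[[`, 0, "one_target_acc"))
      }
      names(p_by) <- conds
      p_mat <- do.call(cbind, p_by)        # n_soa x n_cond
      n_rates <- n_rates + length(p_mat) + 1L
      n_clamped <- n_clamped + sum(p_mat < 0 | p_mat > 1) +
        (one_acc < 0 || one_acc > 1)
      p_mat <- pmin(pmax(p_mat, 0), 1)
      p_row <- p_mat[cbind(match(grid$soa_ms, soa),
                           match(grid$condition, conds))]
      dual <- data.frame(
        participant_id = pid,
        condition = grid$condition,
        n_targets = 2L,
        soa_ms = grid$soa_ms,
        identity_id = grid$identity_id,
        correct = stats::rbinom(nrow(grid), 1L, p_row),
        stringsAsFactors = FALSE
      )
      one <- if (design$n_one_target > 0) {
        data.frame(
          participant_id = pid,
          condition = rep_len(conds, design$n_one_target),
          n_targets = 1L,
          soa_ms = NA_real_,
          identity_id = rep_len(ids, design$n_one_target),
          correct = stats::rbinom(design$n_one_target, 1L,
                                  min(max(one_acc, 0), 1)),
          stringsAsFactors = FALSE
        )
      } else NULL
      out[[k]] <- rbind(dual, one)
    }
    tt <- do.call(rbind, out)
    rownames(tt) <- NULL
    if (n_clamped / n_rates > max_clamp_frac) {
      warnf("%d of %d rate evaluations clamped into [0, 1]; injected amplitude is distorted",
            n_clamped, n_rates)
    }
    structure(tt, n_clamped = n_clamped,
              class = c("trial_table", "data.frame"))
  })
}

#' Noiseless calibration course on the design's SOA grid
#'
#' Returns the pure sinusoid `y(soa) = (ptp/2) sin(2 pi f soa / 1000 +
#' phase)` evaluated on the design's SOA grid, with zero trend, as a
#' detrended course ready for [compute_spectrum()]. Used to calibrate the
#' mapping between spectral amplitude and the peak-to-peak modulation range
#' (see [amplitude_to_variance()]).
#'
#' @param freq_hz Frequency in Hz; must be below the SOA grid's Nyquist
#'   frequency (15 Hz for the default 30 Hz frame rate).
#' @param ptp Peak-to-peak range of the modulation in `[0, 1]`.
#' @param phase_rad Phase in radians at first target onset (t = 0).
#' @param design An [rsvp_design()].
#' @return A `"detrended_course"` whose `residual` holds the sinusoid.
#' @examples
#' cal <- make_calibration_course(4.6, 0.5)
#' max(cal$residual) - min(cal$residual) <= 0.5
#' @export
make_calibration_course <- function(freq_hz, ptp, phase_rad = 0,
                                    design = rsvp_design()) {
  stopifnot(inherits(design, "rsvp_design"))
  nyquist <- 1000 / design$frame_ms / 2
  if (freq_hz >= nyquist) {
    stopf("freq_hz = %g is at or above the Nyquist frequency (%g Hz); an aliased calibration is meaningless",
          freq_hz, nyquist)
  }
  if (ptp < 0 || ptp > 1) stopf("ptp must lie in [0, 1]")
  soa <- design$soa_levels_ms
  new_detrended_course(
    participant_id = "calibration",
    condition = "all",
    soa_ms = soa,
    residual = (ptp / 2) * sin(2 * pi * freq_hz * soa / 1000 + phase_rad)
  )
}
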