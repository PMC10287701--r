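#' Build a dual-target RSVP trial design
#'
#' Enumerates the SOA (stimulus onset asynchrony) grid and trial counts of a
#' dual-target RSVP experiment. Stimuli advance at discrete monitor frames,
#' so SOA levels are stored as exact frame multiples (`k * frame_ms`); the
#' printed values 200 and 833 ms correspond to frames k = 6 and k = 25 at a
#' 30 Hz stream. Equal SOA spacing is required downstream by the FFT.
#'
#' @param frame_ms Stimulus frame duration in ms (default `1000/30`, a 30 Hz
#'   stream).
#' @param soa_min_ms,soa_max_ms SOA range in ms. Both must be integer
#'   multiples of `frame_ms` within `tol_frames` of a frame.
#' @param conditions Character vector of condition labels.
#' @param identities_per_condition Number of distinct target identities per
#'   condition.
#' @param reps_per_identity Repetitions of each identity at each SOA.
#' @param n_one_target Number of one-target baseline trials.
#' @param tol_frames Tolerance, in frames, for accepting a bound as
#'   commensurate with the frame duration (default 0.02 frames, i.e. the
#'   rounding slack of values printed to the nearest ms).
#'
#' @return An object of class `"rsvp_design"`: a list with `soa_levels_ms`,
#'   `n_reps_per_soa`, `n_one_target`, `conditions`,
#'   `identities_per_condition`, `reps_per_identity`, `frame_ms`,
#'   `n_soa_levels` and `n_trials_total`.
#'
#' @examples
#' d <- rsvp_design()
#' d$n_soa_levels   # 20
#' d$n_trials_total # 1008
#' @export
rsvp_design <- function(frame_ms = 1000 / 30,
                        soa_min_ms = 200,
                        soa_max_ms = 833,
                        conditions = c("familiar", "unfamiliar"),
                        identities_per_condition = 12,
                        reps_per_identity = 2,
                        n_one_target = 48,
                        tol_frames = 0.02) {
  if (frame_ms <= 0) stopf("frame_ms must be positive")
  if (!(soa_min_ms < soa_max_ms)) stopf("soa_min_ms must be below soa_max_ms")
  k_min <- round(soa_min_ms / frame_ms)
  k_max <- round(soa_max_ms / frame_ms)
  if (abs(soa_min_ms / frame_ms - k_min) > tol_frames) {
    stopf("soa_min_ms = %g is not commensurate with the %g ms frame",
          soa_min_ms, frame_ms)
  }
  if (abs(soa_max_ms / frame_ms - k_max) > tol_frames) {
    stopf("soa_max_ms = %g is not commensurate with the %g ms frame",
          soa_max_ms, frame_ms)
  }
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stopf("condition labels must be unique")
  soa_levels <- (k_min:k_max) * frame_ms
  n_reps <- length(conditions) * identities_per_condition * reps_per_identity
  structure(
    list(
      soa_levels_ms = soa_levels,
      n_soa_levels = length(soa_levels),
      n_reps_per_soa = n_reps,
      n_one_target = as.integer(n_one_target),
      conditions = conditions,
      identities_per_condition = as.integer(identities_per_condition),
      reps_per_identity = as.integer(reps_per_identity),
      frame_ms = frame_ms,
      n_trials_total = length(soa_levels) * n_reps + as.integer(n_one_target)
    ),
    class = "rsvp_design"
  )
}

#' @export
print.rsvp_design <- function(x, ...) {
  cat("Dual-target RSVP design\n")
  cat(sprintf("  SOA grid : %d levels, %.1f-%.1f ms in %.4g ms frames\n",
              x$n_soa_levels, min(x$soa_levels_ms), max(x$soa_levels_ms),
              x$frame_ms))
  cat(sprintf("  dual-target : %d reps/SOA (%d conditions x %d identities x %d reps)\n",
              x$n_reps_per_soa, length(x$conditions),
              x$identities_per_condition, x$reps_per_identity))
  cat(sprintf("  one-target  : %d trials\n", x$n_one_target))
  cat(sprintf("  total       : %d trials per participant\n", x$n_trials_total))
  invisible(x)
}
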