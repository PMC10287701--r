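#' SOA-shuffle permutation test of the phase-locked sum
#'
#' Builds the null distribution of the band-maximum PLS by independently
#' permuting each participant's detrended residuals across SOA positions
#' and recomputing the spectra and the group PLS on every iteration.
#' Taking the maximum over all tested frequencies corrects for multiple
#' comparisons; the corrected p-value for the observed band peak uses
#' plus-one smoothing, `p = (1 + #\{max >= observed\}) / (1 + n_perm)`,
#' which is a valid finite-sample p-value and always lies in `(0, 1]`. The
#' per-frequency 95th-percentile curve is returned for plotting.
#'
#' @param detrended_courses List of `"detrended_course"` objects on a
#'   common SOA grid (>= 2 participants).
#' @param cfg A [spectral_config()].
#' @param band_hz Band over which the maximum statistic is taken.
#' @param n_perm Number of permutations (>= 100; the reference analysis
#'   uses 10,000).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `"pls_null_test"`: `kind`, corrected `p`,
#'   `observed` (`"pls_curve"`), `peak`, `max_stat` (length `n_perm`),
#'   `per_freq_q95`, `band_hz`, `n_iter`, `seed`.
#' @export
shuffle_null_test <- function(detrended_courses, cfg = spectral_config(),
                              band_hz = cfg$band_hz, n_perm = 10000,
                              seed = NULL) {
  if (length(detrended_courses) < 2L) stopf("need at least 2 participants")
  if (n_perm < 100L) stopf("n_perm must be >= 100 for stable quantiles")
  R <- residual_matrix(detrended_courses)
  .pls_max_null_test(R, cfg, band_hz, n_perm, seed, kind = "soa_shuffle",
                     draw = function(R) {
                       N <- nrow(R)
                       for (j in seq_len(ncol(R))) {
                         R[, j] <- R[sample.int(N), j]
                       }
                       R
                     })
}

# shared engine for max-corrected PLS null tests; `draw` maps the observed
# residual matrix to one null realization
.pls_max_null_test <- function(R, cfg, band_hz, n_iter, seed, kind, draw) {
  M <- cfg$n_padded
  freqs <- .freq_grid(cfg)
  obs_pls <- pls_from_matrix(R, M)
  obs_curve <- structure(list(freqs_hz = freqs, pls = obs_pls, n = ncol(R)),
                         class = "pls_curve")
  peak <- find_peak(obs_curve, band_hz)
  band_idx <- which(freqs >= band_hz[1L] - 1e-9 & freqs <= band_hz[2L] + 1e-9)
  null_curves <- matrix(NA_real_, length(freqs), n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      null_curves[, it] <- pls_from_matrix(draw(R), M)
    }
  })
  max_stat <- apply(null_curves[band_idx, , drop = FALSE], 2L, max)
  structure(
    list(kind = kind,
         p = perm_pvalue(sum(max_stat >= peak$value), n_iter),
         observed = obs_curve,
         peak = peak,
         max_stat = max_stat,
         per_freq_q95 = apply(null_curves, 1L, stats::quantile, probs = 0.95,
                              names = FALSE),
         band_hz = band_hz, n_iter = n_iter, seed = seed),
    class = "pls_null_test"
  )
}

#' @export
print.pls_null_test <- function(x, ...) {
  lab <- switch(x$kind, soa_shuffle = "SOA-shuffle permutation",
                ar1_surrogate = "AR(1)-surrogate", x$kind)
  cat(sprintf("%s test of the phase-locked sum (%d iterations)\n", lab,
              x$n_iter))
  cat(sprintf("  band %g-%g Hz; peak %.4g at %.2f Hz%s\n", x$band_hz[1L],
              x$band_hz[2L], x$peak$value, x$peak$freq_hz,
              if (x$peak$edge) " [band edge]" else ""))
  cat(sprintf("  corrected p = %.4g\n", x$p))
  invisible(x)
}

#' @export
plot.pls_null_test <- function(x, ...) {
  ylim <- range(x$observed$pls, x$per_freq_q95)
  graphics::plot(x$observed$freqs_hz, x$observed$pls, type = "l",
                 xlab = "Frequency (Hz)", ylab = "PLS amplitude (a.u.)",
                 ylim = ylim, ...)
  graphics::lines(x$observed$freqs_hz, x$per_freq_q95, col = "red", lty = 2)
  graphics::abline(v = x$band_hz, lty = 3)
  graphics::points(x$peak$freq_hz, x$peak$value, pch = 19,
                   col = if (x$p < 0.05) "red" else "grey40")
  invisible(x)
}

#' Fit an AR(1) model to a detrended course
#'
#' Conditional least squares: regress `X_t` on `X_{t-1}` for
#' `t = 2, ..., N`, giving the model `X_t = c + phi X_{t-1} + eps_t` with
#' white-noise innovations of SD `sigma_eps`. This preserves the series'
#' aperiodic lag-1 autocorrelation while carrying no periodic structure,
#' which is what makes AR(1) surrogates a conservative null for
#' oscillation detection. Note this `c` is the AR intercept, unrelated to
#' the detrend asymptote.
#'
#' @param detrended A `"detrended_course"` with at least 3 points.
#' @return An object of class `"ar1_params"`: `c_ar`, `phi`, `sigma_eps`,
#'   `stationary` (`|phi| < 1`), `degenerate` (zero-variance input).
#' @export
fit_ar1 <- function(detrended) {
  stopifnot(inherits(detrended, "detrended_course"))
  x <- detrended$residual
  N <- length(x)
  if (N < 3L) stopf("need at least 3 points to fit an AR(1) model")
  if (stats::var(x) < .Machine$double.eps) {
    return(structure(list(c_ar = mean(x), phi = 0, sigma_eps = 0,
                          stationary = TRUE, degenerate = TRUE,
                          participant_id = detrended$participant_id),
                     class = "ar1_params"))
  }
  fit <- stats::lm(x[-1L] ~ x[-N])
  phi <- unname(stats::coef(fit)[2L])
  structure(
    list(c_ar = unname(stats::coef(fit)[1L]), phi = phi,
         sigma_eps = stats::sigma(fit),
         stationary = abs(phi) < 1, degenerate = FALSE,
         participant_id = detrended$participant_id),
    class = "ar1_params"
  )
}

#' @export
print.ar1_params <- function(x, ...) {
  cat(sprintf("AR(1): X_t = %.4g + %.3f X_(t-1) + eps, sigma_eps = %.4g%s%s\n",
              x$c_ar, x$phi, x$sigma_eps,
              if (!x$stationary) " [NON-STATIONARY]" else "",
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

# matrix of AR(1) realizations: N x n, per-column parameters, burn-in discarded
.ar1_draw_matrix <- function(N, pars, burn = 100L) {
  n <- length(pars)
  out <- matrix(NA_real_, N, n)
  for (j in seq_len(n)) {
    p <- pars[[j]]
    eps <- stats::rnorm(N + burn, 0, p$sigma_eps)
    x <- stats::filter(eps, p$phi, method = "recursive")
    mu <- p$c_ar / (1 - p$phi)
    out[, j] <- as.numeric(x[(burn + 1L):(burn + N)]) + mu
  }
  out
}

#' AR(1)-surrogate test of the phase-locked sum
#'
#' Alternative null for the PLS peak that preserves each participant's
#' aperiodic temporal structure: an AR(1) model is fitted to each
#' detrended course ([fit_ar1()]) and every iteration replaces each course
#' with a fresh AR(1) realization (100 burn-in steps discarded) before
#' rerunning the spectra and the PLS. Shuffling in time destroys
#' autocorrelation along with any rhythm, so a peak that also beats this
#' surrogate null cannot be explained by smooth aperiodic structure alone.
#' Multiple-comparison correction and p-value are as in
#' [shuffle_null_test()].
#'
#' @inheritParams shuffle_null_test
#' @param n_surr Number of surrogate iterations (>= 100).
#' @return A `"pls_null_test"` with `kind = "ar1_surrogate"` and the fitted
#'   `ar1_params` attached as attribute `"ar1_fits"`.
#' @export
ar1_surrogate_test <- function(detrended_courses, cfg = spectral_config(),
                               band_hz = cfg$band_hz, n_surr = 10000,
                               seed = NULL) {
  if (length(detrended_courses) < 2L) stopf("need at least 2 participants")
  if (n_surr < 100L) stopf("n_surr must be >= 100 for stable quantiles")
  fits <- lapply(detrended_courses, fit_ar1)
  for (f in fits) {
    if (!f$stationary) {
      stopf("participant %s has a non-stationary AR(1) fit (|phi| >= 1)",
            f$participant_id)
    }
  }
  R <- residual_matrix(detrended_courses)
  N <- nrow(R)
  out <- .pls_max_null_test(R, cfg, band_hz, n_surr, seed,
                            kind = "ar1_surrogate",
                            draw = function(R) .ar1_draw_matrix(N, fits))
  attr(out, "ar1_fits") <- fits
  out
}

#' Rayleigh test of circular non-uniformity
#'
#' Tests whether a sample of phase angles is concentrated rather than
#' uniform on the circle. `R` is the mean resultant length (the modulus of
#' the mean unit vector), `z = n R^2`, and the p-value uses the standard
#' Zar approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`, clamped to
#' `[0, 1]`.
#'
#' @param phases Numeric vector of phase angles in radians (n >= 2, finite).
#' @return An object of class `"rayleigh_test"` with `z`, `p`, `r`, `n`.
#' @examples
#' rayleigh_test(rep(1.2, 10))  # R = 1, z = 10
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2L) stopf("need at least 2 phase angles")
  if (!all(is.finite(phases))) stopf("phases must be finite")
  r <- Mod(mean(exp(1i * phases)))
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  structure(list(z = z, p = min(max(p, 0), 1), r = r, n = n),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, R = %.3f, z = %.3f, p = %.4g\n",
              x$n, x$r, x$z, x$p))
  invisible(x)
}

#' Bootstrap comparison of peak frequencies between two conditions
#'
#' Resamples participants with replacement (the same draw applied to both
#' conditions, respecting the paired within-subject design), recomputes the
#' group PLS per condition, and records the band peak frequency, yielding a
#' bootstrap distribution of peak frequencies per condition. The
#' standardised difference
#' `z = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)` (bootstrap SEs) is
#' compared with the one-sided critical value 1.64.
#'
#' @param courses_a,courses_b Paired lists of `"detrended_course"` objects
#'   (same participants, same order), one per condition.
#' @param cfg A [spectral_config()].
#' @param band_hz Peak search band.
#' @param n_boot Number of bootstrap resamples (>= 100; the reference
#'   analysis uses 1000).
#' @param seed Integer seed or `NULL`.
#' @param z_crit One-sided critical value (default 1.64).
#' @return An object of class `"freq_comparison"` with the bootstrap
#'   distributions, means, SEs, `z`, `significant`, and a `degenerate` flag
#'   when both SEs are zero.
#' @export
bootstrap_peak_comparison <- function(courses_a, courses_b,
                                      cfg = spectral_config(),
                                      band_hz = cfg$band_hz, n_boot = 1000,
                                      seed = NULL, z_crit = 1.64) {
  if (length(courses_a) != length(courses_b)) {
    stopf("paired design: both conditions need the same participants")
  }
  if (n_boot < 100L) stopf("n_boot must be >= 100")
  Ra <- residual_matrix(courses_a)
  Rb <- residual_matrix(courses_b)
  M <- cfg$n_padded
  freqs <- .freq_grid(cfg)
  band_idx <- which(freqs >= band_hz[1L] - 1e-9 & freqs <= band_hz[2L] + 1e-9)
  n <- ncol(Ra)
  fa <- fb <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      pa <- pls_from_matrix(Ra[, idx, drop = FALSE], M)
      pb <- pls_from_matrix(Rb[, idx, drop = FALSE], M)
      fa[b] <- freqs[band_idx[which.max(pa[band_idx])]]
      fb[b] <- freqs[band_idx[which.max(pb[band_idx])]]
    }
  })
  se_a <- stats::sd(fa)
  se_b <- stats::sd(fb)
  denom <- sqrt(se_a^2 + se_b^2)
  dmean <- mean(fa) - mean(fb)
  degenerate <- denom == 0
  z <- if (degenerate) {
    if (dmean == 0) 0 else sign(dmean) * Inf
  } else dmean / denom
  structure(
    list(boot_freqs_a = fa, boot_freqs_b = fb,
         mean_a = mean(fa), mean_b = mean(fb),
         se_a = se_a, se_b = se_b, z = z, z_crit = z_crit,
         significant = z > z_crit, degenerate = degenerate,
         band_hz = band_hz, n_boot = n_boot, seed = seed),
    class = "freq_comparison"
  )
}

#' @export
print.freq_comparison <- function(x, ...) {
  cat(sprintf("Bootstrap peak-frequency comparison (%d resamples, band %g-%g Hz)\n",
              x$n_boot, x$band_hz[1L], x$band_hz[2L]))
  cat(sprintf("  mean peak A %.2f Hz (SE %.3f) vs B %.2f Hz (SE %.3f)\n",
              x$mean_a, x$se_a, x$mean_b, x$se_b))
  cat(sprintf("  z = %.3f (one-sided critical %.2f): %s%s\n", x$z, x$z_crit,
              if (x$significant) "different" else "no detected difference",
              if (x$degenerate) " [zero bootstrap SE]" else ""))
  invisible(x)
}

#' Two one-sided tests (TOST) of peak-frequency equivalence
#'
#' Declares the two conditions' peak frequencies equivalent when the mean
#' difference is significantly above `-margin_hz` AND significantly below
#' `+margin_hz`, each one-sided z-test at level `alpha` using the combined
#' bootstrap SE. With a zero SE the decision falls back to
#' `|difference| < margin` and is flagged.
#'
#' @param comparison A `"freq_comparison"` from
#'   [bootstrap_peak_comparison()].
#' @param margin_hz Equivalence margin in Hz (default 0.5).
#' @param alpha One-sided level (default 0.05).
#' @return An object of class `"tost_result"` with `equivalent`, the mean
#'   `diff`, combined `se`, the two z statistics and p-values, and a
#'   `degenerate` flag.
#' @export
tost_equivalence <- function(comparison, margin_hz = 0.5, alpha = 0.05) {
  stopifnot(inherits(comparison, "freq_comparison"))
  d <- comparison$mean_a - comparison$mean_b
  se <- sqrt(comparison$se_a^2 + comparison$se_b^2)
  crit <- stats::qnorm(1 - alpha)
  if (se == 0) {
    return(structure(list(equivalent = abs(d) < margin_hz, diff = d, se = 0,
                          z_lower = NA_real_, z_upper = NA_real_,
                          p_lower = NA_real_, p_upper = NA_real_,
                          margin_hz = margin_hz, alpha = alpha,
                          degenerate = TRUE),
                     class = "tost_result"))
  }
  z_lower <- (d + margin_hz) / se   # H0: d <= -margin
  z_upper <- (margin_hz - d) / se   # H0: d >= +margin
  structure(
    list(equivalent = z_lower > crit && z_upper > crit, diff = d, se = se,
         z_lower = z_lower, z_upper = z_upper,
         p_lower = stats::pnorm(z_lower, lower.tail = FALSE),
         p_upper = stats::pnorm(z_upper, lower.tail = FALSE),
         margin_hz = margin_hz, alpha = alpha, degenerate = FALSE),
    class = "tost_result"
  )
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("TOST equivalence (margin %.2f Hz, alpha %.2f): diff %.3f Hz -> %s%s\n",
              x$margin_hz, x$alpha, x$diff,
              if (x$equivalent) "EQUIVALENT" else "not equivalent",
              if (x$degenerate) " [zero SE, decided analytically]" else ""))
  invisible(x)
}

# chain: trial table -> per-condition ITC at one padded frequency bin
.itc_pair <- function(trials, conditions, bin, cfg) {
  vapply(conditions, function(cc) {
    courses <- aggregate_accuracy(trials, condition_filter = cc,
                                  n_targets_filter = 2)
    det <- detrend_cohort(courses)
    R <- residual_matrix(det)
    ph <- Arg(coeff_at_bin(R, cfg$n_padded, bin))
    Mod(mean(exp(1i * ph)))
  }, numeric(1L))
}

#' Inter-trial phase coherence contrast (PLD) between two conditions
#'
#' For each condition, reruns the full chain (per-participant accuracy
#' courses, exponential detrend, zero-padded spectrum) and extracts the
#' phase at `peak_freq_hz`; the ITC is the mean resultant length of those
#' phases across participants, and the phase-locking difference is
#' `PLD = ITC_a - ITC_b` (condition order as given). The null permutes
#' condition labels across each participant's dual-target trials —
#' participants are not exchangeable, trials within a participant are —
#' and reruns the same chain; the one-sided p-value is
#' `(1 + #\{null PLD >= observed\}) / (1 + n_perm)`. Permutations that
#' empty any (participant, condition, SOA) cell are redrawn and counted.
#'
#' @param trials A trial table with exactly the two `conditions` present.
#' @param peak_freq_hz Frequency at which phases are extracted; must lie on
#'   the padded frequency grid.
#' @param conditions Length-2 character vector; PLD is condition 1 minus
#'   condition 2.
#' @param cfg A [spectral_config()].
#' @param n_perm Number of label permutations (the reference analysis uses
#'   10,000).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `"pld_result"` with `itc_a`, `itc_b`, `pld`,
#'   `null_plds`, one-sided `p` and the count of redrawn permutations.
#' @export
itc_pld_test <- function(trials, peak_freq_hz,
                         conditions = NULL, cfg = spectral_config(),
                         n_perm = 10000, seed = NULL) {
  dual <- trials[trials$n_targets == 2, , drop = FALSE]
  if (is.null(conditions)) conditions <- sort(unique(dual$condition))
  if (length(conditions) != 2L) {
    stopf("exactly two condition labels are required")
  }
  freqs <- .freq_grid(cfg)
  bin <- which(abs(freqs - peak_freq_hz) < 1e-9)
  if (length(bin) != 1L) {
    stopf("peak_freq_hz = %g Hz does not lie on the %g Hz frequency grid",
          peak_freq_hz, cfg$freq_resolution_hz)
  }
  itc <- .itc_pair(trials, conditions, bin, cfg)
  pld <- itc[[1L]] - itc[[2L]]
  pids <- unique(dual$participant_id)
  by_pid <- split(seq_len(nrow(dual)), dual$participant_id)[pids]
  null_plds <- numeric(n_perm)
  n_redrawn <- 0L
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      perm <- dual
      for (rows in by_pid) {
        ok <- FALSE
        for (try in 1:100) {
          lab <- dual$condition[rows][sample.int(length(rows))]
          tab <- table(lab, dual$soa_ms[rows])
          if (all(tab > 0L)) { ok <- TRUE; break }
          n_redrawn <- n_redrawn + 1L
        }
        if (!ok) stopf("could not find a label permutation keeping all cells non-empty")
        perm$condition[rows] <- lab
      }
      it_itc <- .itc_pair(perm, conditions, bin, cfg)
      null_plds[it] <- it_itc[[1L]] - it_itc[[2L]]
    }
  })
  structure(
    list(itc_a = itc[[1L]], itc_b = itc[[2L]], pld = pld,
         null_plds = null_plds,
         p = perm_pvalue(sum(null_plds >= pld), n_perm),
         conditions = conditions, peak_freq_hz = peak_freq_hz,
         n_perm = n_perm, n_redrawn = n_redrawn, seed = seed),
    class = "pld_result"
  )
}

#' @export
print.pld_result <- function(x, ...) {
  cat(sprintf("Phase-locking difference at %.2f Hz (%d permutations)\n",
              x$peak_freq_hz, x$n_perm))
  cat(sprintf("  ITC(%s) = %.3f, ITC(%s) = %.3f, PLD = %.4f, one-sided p = %.4g\n",
              x$conditions[1L], x$itc_a, x$conditions[2L], x$itc_b, x$pld,
              x$p))
  if (x$n_redrawn > 0L) {
    cat(sprintf("  (%d permutations redrawn to keep cells non-empty)\n",
                x$n_redrawn))
  }
  invisible(x)
}

#' One-sided paired t-test on accuracies
#'
#' Standard paired t-test of `a - b` with an upper one-sided alternative
#' (`a > b`). Zero-variance differences give an infinite-t degenerate
#' case, flagged and resolved by sign (p near 0 for a positive mean
#' difference, near 1 for a negative one, 0.5 for all-zero differences).
#'
#' @param acc_a,acc_b Paired accuracy vectors of equal length (n >= 2).
#' @return A list with `t`, `df`, `p`, `mean_diff` and `degenerate`.
#' @export
paired_one_sided_t <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stopf("paired vectors must have equal length")
  n <- length(acc_a)
  if (n < 2L) stopf("need at least 2 pairs")
  d <- acc_a - acc_b
  if (stats::sd(d) < .Machine$double.eps) {
    m <- mean(d)
    p <- if (m > 0) .Machine$double.eps else if (m < 0) 1 else 0.5
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1L, p = p,
                mean_diff = m, degenerate = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Bootstrap power analysis over candidate sample sizes
#'
#' For each candidate sample size `n`, repeatedly draws `n` participants
#' with replacement from the cohort's detrended courses, runs the
#' PLS + SOA-shuffle analysis (at reduced permutation counts), and counts
#' runs whose corrected p-value falls below `alpha`. Power at `n` is the
#' positive fraction.
#'
#' @param detrended_courses The cohort's detrended courses.
#' @param sample_sizes Integer vector of candidate sample sizes.
#' @param n_boot Resamples per sample size (the reference plan uses 2000).
#' @param alpha Corrected significance level (default 0.05).
#' @param cfg A [spectral_config()].
#' @param band_hz Peak band.
#' @param n_perm Permutations per resampled analysis (default 200).
#' @param seed Integer seed or `NULL`.
#' @return A `data.frame` with columns `n` and `power`.
#' @export
power_by_bootstrap <- function(detrended_courses, sample_sizes, n_boot,
                               alpha = 0.05, cfg = spectral_config(),
                               band_hz = cfg$band_hz, n_perm = 200,
                               seed = NULL) {
  n_avail <- length(detrended_courses)
  power <- numeric(length(sample_sizes))
  with_seed(seed, {
    for (i in seq_along(sample_sizes)) {
      n <- sample_sizes[i]
      hits <- 0L
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n_avail, n, replace = TRUE)
        res <- shuffle_null_test(detrended_courses[idx], cfg = cfg,
                                 band_hz = band_hz, n_perm = n_perm,
                                 seed = NULL)
        if (res$p < alpha) hits <- hits + 1L
      }
      power[i] <- hits / n_boot
    }
  })
  data.frame(n = sample_sizes, power = power)
}
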