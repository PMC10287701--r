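# Orthonormal bases (sin, cos, intercept) per candidate frequency, stacked
# as a (3F x N) matrix so that all frequencies' R^2 for a new response come
# from one matrix product. t_sec is time in seconds from the first SOA.
.sine_basis_stack <- function(t_sec, freqs) {
  N <- length(t_sec)
  G <- matrix(NA_real_, 3L * length(freqs), N)
  rank3 <- logical(length(freqs))
  for (i in seq_along(freqs)) {
    X <- cbind(sin(2 * pi * freqs[i] * t_sec), cos(2 * pi * freqs[i] * t_sec),
               1)
    qd <- qr(X)
    Q <- qr.Q(qd)
    rank3[i] <- qd$rank == 3L
    rows <- (3L * i - 2L):(3L * i)
    G[rows, ] <- 0
    G[rows[seq_len(qd$rank)], ] <- t(Q[, seq_len(qd$rank), drop = FALSE])
  }
  list(G = G, rank3 = rank3)
}

# R^2 per frequency for response y, given a basis stack
.r2_per_freq <- function(basis, y) {
  sst <- sum((y - mean(y))^2)
  v <- basis$G %*% y               # projections onto each orthonormal basis
  ssr_full <- colSums(matrix(v^2, nrow = 3L))   # ||Q^T y||^2 per frequency
  sse <- sum(y^2) - ssr_full
  if (sst <= 0) return(rep(0, length(ssr_full)))
  pmin(pmax(1 - sse / sst, 0), 1)
}

.adj_r2 <- function(r2, n, p = 3L) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Sinusoidal fit to a group detrended course
#'
#' Complementary time-domain check on an oscillation: at each candidate
#' frequency on `freq_grid`, fits `a sin(2 pi f t) + b cos(2 pi f t) + d`
#' by ordinary least squares (`t` in seconds from the first SOA), which is
#' linear in the coefficients and hence convex and deterministic per
#' frequency. The best frequency maximises R-squared (ties toward the
#' lower frequency); the amplitude is `sqrt(a^2 + b^2)` and the phase
#' `atan2(b, a)`, so the fitted curve is
#' `amplitude * sin(2 pi f t + phase) + d`. The adjusted R-squared uses
#' `p = 3` fitted coefficients. A permutation p-value can be attached via
#' [sinusoid_permutation_p()].
#'
#' @param group_detrended A `"detrended_course"` (typically the
#'   group-average residuals, see [average_courses()]).
#' @param freq_grid Candidate frequencies in Hz, within `(0, Nyquist)`;
#'   default `seq(3, 13, by = 0.01)`.
#' @return An object of class `"sinusoid_fit"`: `freq_hz`, `amplitude`,
#'   `phase_rad`, `intercept`, `r2`, `adj_r2`, `p_perm` (`NA` until
#'   computed), coefficient vector `coef_abd`, and the time origin
#'   `t0_ms`.
#' @export
fit_sinusoid <- function(group_detrended, freq_grid = seq(3, 13, by = 0.01)) {
  stopifnot(inherits(group_detrended, "detrended_course"))
  soa <- group_detrended$soa_ms
  y <- group_detrended$residual
  n <- length(y)
  fs <- 1000 / (soa[2L] - soa[1L])
  if (any(freq_grid <= 0) || any(freq_grid > fs / 2)) {
    stopf("freq_grid must lie in (0, %g] Hz (Nyquist)", fs / 2)
  }
  t_sec <- (soa - soa[1L]) / 1000
  basis <- .sine_basis_stack(t_sec, freq_grid)
  r2 <- .r2_per_freq(basis, y)
  i <- which.max(r2)              # first max = lowest frequency on ties
  f <- freq_grid[i]
  X <- cbind(s = sin(2 * pi * f * t_sec), c = cos(2 * pi * f * t_sec))
  cf <- stats::coef(stats::lm(y ~ X))
  a <- unname(cf["Xs"]); b <- unname(cf["Xc"]); d <- unname(cf["(Intercept)"])
  if (anyNA(c(a, b))) { a <- ifelse(is.na(a), 0, a); b <- ifelse(is.na(b), 0, b) }
  structure(
    list(freq_hz = f, amplitude = sqrt(a^2 + b^2),
         phase_rad = atan2(b, a), intercept = d,
         r2 = r2[i], adj_r2 = .adj_r2(r2[i], n), p_perm = NA_real_,
         coef_abd = c(a = a, b = b, d = d),
         freq_grid_range = range(freq_grid), n = n, t0_ms = soa[1L]),
    class = "sinusoid_fit"
  )
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("Sinusoidal fit: %.2f Hz, amplitude %.4g, adj R^2 = %.3f",
              x$freq_hz, x$amplitude, x$adj_r2))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' @export
coef.sinusoid_fit <- function(object, ...) {
  c(freq_hz = object$freq_hz, amplitude = object$amplitude,
    phase_rad = object$phase_rad, intercept = object$intercept)
}

#' @export
predict.sinusoid_fit <- function(object, soa_ms, ...) {
  t_sec <- (soa_ms - object$t0_ms) / 1000
  object$amplitude * sin(2 * pi * object$freq_hz * t_sec + object$phase_rad) +
    object$intercept
}

#' Permutation p-value for the best sinusoidal fit
#'
#' Permutes the group course across SOA positions, refits over the whole
#' frequency grid, and records the maximum adjusted R-squared per
#' permutation; `p = (1 + exceedances) / (1 + n_perm)`. Because n and the
#' coefficient count are fixed, maximising adjusted R-squared is
#' equivalent to maximising R-squared.
#'
#' @inheritParams fit_sinusoid
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed or `NULL`.
#' @return The permutation p-value, with the null maxima in attribute
#'   `"null_max_adj_r2"` and the observed maximum in `"observed"`.
#' @export
sinusoid_permutation_p <- function(group_detrended,
                                   freq_grid = seq(3, 13, by = 0.01),
                                   n_perm = 10000, seed = NULL) {
  stopifnot(inherits(group_detrended, "detrended_course"))
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  soa <- group_detrended$soa_ms
  y <- group_detrended$residual
  n <- length(y)
  t_sec <- (soa - soa[1L]) / 1000
  basis <- .sine_basis_stack(t_sec, freq_grid)
  obs <- .adj_r2(max(.r2_per_freq(basis, y)), n)
  null_max <- numeric(n_perm)
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      null_max[it] <- .adj_r2(max(.r2_per_freq(basis, y[sample.int(n)])), n)
    }
  })
  p <- perm_pvalue(sum(null_max >= obs), n_perm)
  attr(p, "null_max_adj_r2") <- null_max
  attr(p, "observed") <- obs
  p
}

#' Sliding-window fit between the data and the best-fit sinusoid
#'
#' Quantifies how the sinusoidal fit decays with distance from the phase
#' reset at first-target onset. The detrended series is zero-padded by
#' half a window at both ends so every SOA can serve as a window centre;
#' at each centre, the goodness of fit is the squared Pearson correlation
#' between the windowed data and the corresponding segment of the fixed
#' best-fit sinusoid (no per-window refit). The significance threshold is
#' the 95th percentile, over AR(1) surrogate courses, of each surrogate's
#' maximum windowed fit across centres (a familywise threshold).
#'
#' @param group_detrended The group `"detrended_course"`.
#' @param best_fit The `"sinusoid_fit"` obtained on the same course.
#' @param surrogate_courses List of surrogate `"detrended_course"` objects
#'   on the same grid (e.g. from [ar1_surrogate_courses()]).
#' @param window_ms Window length in ms; must span an odd number of
#'   samples (default 233 ms = 7 samples at a 30 Hz frame rate).
#' @return An object of class `"sliding_fit"`: `centers_ms`, `window_ms`,
#'   `r2_per_center`, `threshold_r2`, `significant`.
#' @export
sliding_window_fit <- function(group_detrended, best_fit, surrogate_courses,
                               window_ms = 233) {
  stopifnot(inherits(group_detrended, "detrended_course"),
            inherits(best_fit, "sinusoid_fit"))
  soa <- group_detrended$soa_ms
  frame <- soa[2L] - soa[1L]
  w <- round(window_ms / frame)
  if (w %% 2L == 0L) stopf("window_ms must span an odd number of samples")
  if (w > length(soa)) stopf("window (%d samples) is longer than the series",
                             w)
  h <- (w - 1L) %/% 2L
  soa_ext <- seq(soa[1L] - h * frame, soa[length(soa)] + h * frame,
                 by = frame)
  sine_ext <- predict(best_fit, soa_ext) - best_fit$intercept
  window_r2 <- function(y) {
    y_ext <- c(rep(0, h), y, rep(0, h))
    vapply(seq_along(soa), function(i) {
      seg_y <- y_ext[i:(i + w - 1L)]
      seg_s <- sine_ext[i:(i + w - 1L)]
      if (stats::sd(seg_y) == 0 || stats::sd(seg_s) == 0) return(0)
      stats::cor(seg_y, seg_s)^2
    }, numeric(1L))
  }
  r2 <- window_r2(group_detrended$residual)
  surr_max <- vapply(surrogate_courses,
                     function(s) max(window_r2(s$residual)), numeric(1L))
  thr <- stats::quantile(surr_max, 0.95, names = FALSE)
  structure(
    list(centers_ms = soa, window_ms = w * frame, r2_per_center = r2,
         threshold_r2 = thr, significant = r2 > thr,
         n_surrogates = length(surrogate_courses)),
    class = "sliding_fit"
  )
}

#' @export
print.sliding_fit <- function(x, ...) {
  cat(sprintf("Sliding-window fit (%.0f ms windows, %d surrogates)\n",
              x$window_ms, x$n_surrogates))
  sig <- x$centers_ms[x$significant]
  cat(sprintf("  threshold R^2 = %.3f; significant centres: %s\n",
              x$threshold_r2,
              if (length(sig)) paste(round(sig), collapse = ", ") else "none"))
  invisible(x)
}

#' @export
plot.sliding_fit <- function(x, ...) {
  graphics::plot(x$centers_ms, x$r2_per_center, type = "b", xlab = "SOA (ms)",
                 ylab = expression(R^2), ...)
  graphics::abline(h = x$threshold_r2, col = "red", lty = 2)
  invisible(x)
}

#' AR(1) surrogate courses for one detrended course
#'
#' Draws `n_surrogates` AR(1) realizations from the model fitted to the
#' course (100 burn-in steps discarded), returned as detrended courses on
#' the same SOA grid. Used to threshold the sliding-window analysis.
#'
#' @param detrended A `"detrended_course"`.
#' @param n_surrogates Number of surrogate courses.
#' @param seed Integer seed or `NULL`.
#' @return A list of `"detrended_course"` objects.
#' @export
ar1_surrogate_courses <- function(detrended, n_surrogates, seed = NULL) {
  fit <- fit_ar1(detrended)
  if (!fit$stationary) stopf("AR(1) fit is non-stationary; cannot simulate")
  N <- length(detrended$residual)
  with_seed(seed, {
    lapply(seq_len(n_surrogates), function(i) {
      x <- .ar1_draw_matrix(N, list(fit))[, 1L]
      new_detrended_course(sprintf("%s_surr%04d", detrended$participant_id, i),
                           detrended$condition, detrended$soa_ms, x)
    })
  })
}

#' Average detrended courses across participants
#'
#' Pointwise mean of the residuals, for the group-level sinusoidal fit.
#'
#' @param detrended_courses List of `"detrended_course"` objects on a
#'   common grid.
#' @return A single `"detrended_course"` with `participant_id = "group"`.
#' @export
average_courses <- function(detrended_courses) {
  R <- residual_matrix(detrended_courses)
  new_detrended_course("group", detrended_courses[[1L]]$condition,
                       detrended_courses[[1L]]$soa_ms, rowMeans(R))
}
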