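#' @noRd
new_accuracy_course <- function(participant_id, condition, soa_ms, accuracy,
                                n_trials) {
  structure(
    list(participant_id = participant_id, condition = condition,
         soa_ms = soa_ms, accuracy = accuracy, n_trials = n_trials),
    class = "accuracy_course"
  )
}

#' @noRd
new_detrended_course <- function(participant_id, condition, soa_ms, residual) {
  structure(
    list(participant_id = participant_id, condition = condition,
         soa_ms = soa_ms, residual = residual),
    class = "detrended_course"
  )
}

#' @export
print.accuracy_course <- function(x, ...) {
  cat(sprintf("Accuracy course: participant %s, condition %s\n",
              x$participant_id, x$condition))
  cat(sprintf("  %d SOA levels, accuracy %.3f-%.3f (mean %.3f)\n",
              length(x$soa_ms), min(x$accuracy), max(x$accuracy),
              mean(x$accuracy)))
  invisible(x)
}

#' @export
print.detrended_course <- function(x, ...) {
  cat(sprintf("Detrended course: participant %s, condition %s (%d SOA levels, residual SD %.4f)\n",
              x$participant_id, x$condition, length(x$soa_ms),
              stats::sd(x$residual)))
  invisible(x)
}

#' Aggregate trial records into accuracy measures
#'
#' For dual-target trials (`n_targets_filter = 2`), computes each
#' participant's mean accuracy at every SOA level and returns one
#' `accuracy_course` per participant. For one-target trials
#' (`n_targets_filter = 1`), returns a named vector of per-participant
#' accuracies. Aggregation is deterministic.
#'
#' @param trials A trial table (see [simulate_cohort()] / [read_trials()]).
#' @param condition_filter Optional condition label(s) to keep; `NULL`
#'   pools all conditions.
#' @param n_targets_filter 2 (default) for SOA courses, 1 for one-target
#'   baseline accuracies.
#' @return A list of `"accuracy_course"` objects (dual-target) or a named
#'   numeric vector (one-target).
#' @export
aggregate_accuracy <- function(trials, condition_filter = NULL,
                               n_targets_filter = 2) {
  stopifnot(is.data.frame(trials))
  keep <- trials$n_targets == n_targets_filter
  if (!is.null(condition_filter)) {
    keep <- keep & trials$condition %in% condition_filter
  }
  tt <- trials[keep, , drop = FALSE]
  if (nrow(tt) == 0L) stopf("no trials match the requested filter")
  cond_label <- if (is.null(condition_filter)) "all" else
    paste(condition_filter, collapse = "+")
  if (n_targets_filter == 1) {
    acc <- tapply(tt$correct, tt$participant_id, mean)
    return(acc[order(names(acc))])
  }
  soa_grid <- sort(unique(tt$soa_ms))
  pids <- sort(unique(tt$participant_id))
  lapply(stats::setNames(pids, pids), function(pid) {
    rows <- tt[tt$participant_id == pid, , drop = FALSE]
    idx <- match(rows$soa_ms, soa_grid)
    n_per <- tabulate(idx, nbins = length(soa_grid))
    if (any(n_per == 0L)) {
      stopf("participant %s has no trials at SOA %g ms under this filter",
            pid, soa_grid[which(n_per == 0L)[1L]])
    }
    acc <- as.numeric(tapply(rows$correct, factor(idx,
                                                  levels = seq_along(soa_grid)),
                             mean))
    new_accuracy_course(pid, cond_label, soa_grid, acc, n_per)
  })
}

# SSE of the exponential decay model at parameters p = (a0, tau, c)
.exp_sse <- function(p, x, y) {
  f <- p[1L] * exp(-x / p[2L]) + p[3L]
  sum((y - f)^2)
}

#' Fit an exponential decay trend to an accuracy course
#'
#' Least-squares fit of `f(x) = a0 * exp(-x / tau) + c` to a
#' participant's accuracy over SOA `x`, where `a0` is the starting
#' amplitude, `tau` the decay time constant (ms) and `c` the asymptotic
#' baseline. The exponential is prone to flat likelihoods and local minima,
#' so the bounded optimisation (`a0` in `[-1, 1]`, `tau` in `[10, 1e4]` ms,
#' `c` in `[0, 1]`) is restarted from a grid of initial values
#' (`a0 in {y_1 - y_N, 0}`, `tau in {100, 300, 1000}` ms, `c = y_N`) and
#' the lowest-SSE solution kept. If no start beats the nested constant
#' model (`a0 = 0`, `c = mean(y)`), the constant model is returned with
#' `converged = FALSE`, so the fitted SSE never exceeds the constant
#' model's.
#'
#' @param course An `"accuracy_course"` with at least 4 SOA points.
#' @return An object of class `"trend_fit"` with elements `a0`, `tau_ms`,
#'   `c`, `converged`, `sse`, `soa_ms` and `fitted`.
#' @examples
#' soa <- rsvp_design()$soa_levels_ms
#' y <- 0.2 * exp(-soa / 150) + 0.65
#' cr <- structure(list(participant_id = "P1", condition = "all",
#'                      soa_ms = soa, accuracy = y,
#'                      n_trials = rep(48, 20)), class = "accuracy_course")
#' coef(fit_exponential_trend(cr))
#' @export
fit_exponential_trend <- function(course) {
  stopifnot(inherits(course, "accuracy_course"))
  x <- course$soa_ms
  y <- course$accuracy
  n <- length(y)
  if (n < 4L) stopf("need at least 4 SOA points to fit 3 parameters")
  lower <- c(-1, 10, 0)
  upper <- c(1, 1e4, 1)
  c0 <- min(max(y[n], 0), 1)
  starts <- expand.grid(a0 = c(y[1L] - y[n], 0), tau = c(100, 300, 1000))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- c(min(max(starts$a0[s], lower[1L]), upper[1L]), starts$tau[s], c0)
    fit <- tryCatch(
      stats::optim(p0, .exp_sse, x = x, y = y, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  # polish the winning start to tight tolerance (cheap relative to 6 starts)
  if (!is.null(best)) {
    polished <- tryCatch(
      stats::optim(best$par, .exp_sse, x = x, y = y, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1, maxit = 500L)),
      error = function(e) NULL
    )
    if (!is.null(polished) && polished$value <= best$value) best <- polished
  }
  const_sse <- .exp_sse(c(0, 100, min(max(mean(y), 0), 1)), x, y)
  if (is.null(best) || best$value > const_sse) {
    p <- c(0, 100, min(max(mean(y), 0), 1))
    sse <- const_sse
    converged <- FALSE
  } else {
    p <- best$par
    sse <- best$value
    converged <- best$convergence == 0L
  }
  structure(
    list(a0 = p[1L], tau_ms = p[2L], c = p[3L], converged = converged,
         sse = sse, soa_ms = x,
         fitted = p[1L] * exp(-x / p[2L]) + p[3L]),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat("Exponential decay trend: f(x) = a0 * exp(-x/tau) + c\n")
  print(round(coef(x), digits))
  cat(sprintf("  SSE %.3g, %sconverged\n", x$sse,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(a0 = object$a0, tau_ms = object$tau_ms, c = object$c)
}

#' @export
predict.trend_fit <- function(object, soa_ms = object$soa_ms, ...) {
  object$a0 * exp(-soa_ms / object$tau_ms) + object$c
}

#' @export
fitted.trend_fit <- function(object, ...) object$fitted

#' Remove a fitted trend from an accuracy course
#'
#' Subtracts the fitted exponential trend from the raw accuracy, point by
#' point, to expose the oscillatory residual. No smoothing or filtering is
#' applied. The trend must have been fitted on the same SOA grid.
#'
#' @param course An `"accuracy_course"`.
#' @param trend The matching `"trend_fit"`.
#' @return A `"detrended_course"` with element `residual`.
#' @export
detrend <- function(course, trend) {
  stopifnot(inherits(course, "accuracy_course"), inherits(trend, "trend_fit"))
  if (length(course$soa_ms) != length(trend$soa_ms) ||
      max(abs(course$soa_ms - trend$soa_ms)) > 1e-9) {
    stopf("trend was fitted on a different SOA grid than the course")
  }
  new_detrended_course(course$participant_id, course$condition,
                       course$soa_ms, course$accuracy - trend$fitted)
}

#' Detrend every course in a cohort
#'
#' Convenience wrapper: fits the exponential trend to each accuracy course
#' and subtracts it.
#'
#' @param courses A list of `"accuracy_course"` objects
#'   (from [aggregate_accuracy()]).
#' @return A named list of `"detrended_course"` objects, with attribute
#'   `trend_fits` holding the per-participant `"trend_fit"`s.
#' @export
detrend_cohort <- function(courses) {
  fits <- lapply(courses, fit_exponential_trend)
  out <- mapply(detrend, courses, fits, SIMPLIFY = FALSE)
  attr(out, "trend_fits") <- fits
  out
}

# N x n matrix of residuals, one column per participant
residual_matrix <- function(detrended_courses) {
  soa <- detrended_courses[[1L]]$soa_ms
  for (d in detrended_courses) {
    if (length(d$soa_ms) != length(soa) || max(abs(d$soa_ms - soa)) > 1e-9) {
      stopf("detrended courses are not on a common SOA grid")
    }
  }
  vapply(detrended_courses, `[[`, numeric(length(soa)), "residual")
}
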