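#' Write a trial table to CSV
#'
#' Columns `participant_id, condition, n_targets, soa_ms, identity_id,
#' correct`; the missing SOA of one-target trials is written as an empty
#' field.
#'
#' @param trials A trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "condition", "n_targets", "soa_ms",
            "identity_id", "correct")
  utils::write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Validates the documented header, binary `correct`, `n_targets` in
#' `{1, 2}`, known condition labels, and that every dual-target SOA lies
#' on the design's grid (off-grid rows are rejected by row number).
#' Participants whose accuracy at the shortest SOA — the easiest
#' condition — falls below `min_soa_acc` are excluded with a message;
#' their ids are recorded in the attribute `"excluded"`.
#'
#' @param path CSV path written by [write_trials()] (or equivalent).
#' @param design The [rsvp_design()] the data should follow.
#' @param min_soa_acc Inclusion threshold on accuracy at the shortest SOA
#'   (default 0.5).
#' @return A validated `"trial_table"` data frame.
#' @export
read_trials <- function(path, design = rsvp_design(), min_soa_acc = 0.5) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "n_targets", "soa_ms",
            "identity_id", "correct")
  if (!identical(sort(names(tt)), sort(need))) {
    stopf("malformed header: expected columns %s", paste(need, collapse = ", "))
  }
  tt <- tt[, need]
  tt$participant_id <- as.character(tt$participant_id)
  bad <- which(!tt$correct %in% c(0L, 1L))
  if (length(bad)) stopf("non-binary 'correct' in rows %s",
                         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!tt$n_targets %in% c(1L, 2L))
  if (length(bad)) stopf("'n_targets' outside {1, 2} in rows %s",
                         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!tt$condition %in% design$conditions)
  if (length(bad)) {
    stopf("unknown condition label '%s' in rows %s",
          tt$condition[bad[1L]], paste(utils::head(bad, 5L), collapse = ", "))
  }
  dual <- tt$n_targets == 2L
  if (any(is.na(tt$soa_ms[dual]))) {
    stopf("missing soa_ms in dual-target rows %s",
          paste(utils::head(which(dual & is.na(tt$soa_ms)), 5L),
                collapse = ", "))
  }
  snapped <- vapply(tt$soa_ms[dual], function(s) {
    i <- which.min(abs(design$soa_levels_ms - s))
    if (abs(design$soa_levels_ms[i] - s) > 1e-3) NA_real_
    else design$soa_levels_ms[i]
  }, numeric(1L))
  if (anyNA(snapped)) {
    off <- which(dual)[which(is.na(snapped))]
    stopf("SOA off the design grid (e.g. %g ms) in rows %s",
          tt$soa_ms[off[1L]], paste(utils::head(off, 5L), collapse = ", "))
  }
  tt$soa_ms[dual] <- snapped
  # inclusion rule: performance at the shortest (easiest) SOA
  min_soa <- design$soa_levels_ms[1L]
  at_min <- tt[dual & abs(tt$soa_ms - min_soa) < 1e-9, , drop = FALSE]
  acc_min <- tapply(at_min$correct, at_min$participant_id, mean)
  excluded <- names(acc_min)[acc_min < min_soa_acc]
  if (length(excluded)) {
    message(sprintf("excluding %d participant(s) with accuracy below %.0f%% at the %g ms SOA: %s",
                    length(excluded), 100 * min_soa_acc, min_soa,
                    paste(excluded, collapse = ", ")))
    tt <- tt[!tt$participant_id %in% excluded, , drop = FALSE]
  }
  rownames(tt) <- NULL
  structure(tt, excluded = excluded, class = c("trial_table", "data.frame"))
}

#' Analysis configuration
#'
#' Bundles the bands, iteration counts and seed of a full analysis run.
#' The `"full"` profile uses the reference iteration counts (10,000
#' permutations and surrogates, 1,000 bootstrap resamples); the `"ci"`
#' profile scales them down (500/500/200, 500 sliding-window surrogates)
#' for desk-scale runs. Individual counts can be overridden.
#'
#' @param profile `"full"` or `"ci"`.
#' @param band_hz Band of interest (default `c(3, 13)`).
#' @param full_range_hz Reporting range (default `c(0, 15)`).
#' @param n_perm,n_surr,n_boot,n_surr_slide,n_perm_sine Iteration counts;
#'   `NULL` takes the profile default.
#' @param sine_freq_step_hz Grid step of the sinusoidal fit (default
#'   0.01 Hz).
#' @param seed Integer seed driving every stochastic stage.
#' @param combined_detrend `"pooled"` (default) detrends the pooled
#'   accuracy courses for the combined analysis; `"average"` averages the
#'   per-condition detrended residuals instead.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(profile = c("full", "ci"),
                            band_hz = c(3, 13), full_range_hz = c(0, 15),
                            n_perm = NULL, n_surr = NULL, n_boot = NULL,
                            n_surr_slide = NULL, n_perm_sine = NULL,
                            sine_freq_step_hz = 0.01,
                            seed = 1L,
                            combined_detrend = c("pooled", "average")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(n_perm = 10000L, n_surr = 10000L, n_boot = 1000L,
         n_surr_slide = 1000L, n_perm_sine = 10000L)
  } else {
    list(n_perm = 500L, n_surr = 500L, n_boot = 200L,
         n_surr_slide = 500L, n_perm_sine = 500L)
  }
  structure(
    list(profile = profile, band_hz = band_hz, full_range_hz = full_range_hz,
         n_perm = if (is.null(n_perm)) defaults$n_perm else as.integer(n_perm),
         n_surr = if (is.null(n_surr)) defaults$n_surr else as.integer(n_surr),
         n_boot = if (is.null(n_boot)) defaults$n_boot else as.integer(n_boot),
         n_surr_slide = if (is.null(n_surr_slide)) defaults$n_surr_slide
                        else as.integer(n_surr_slide),
         n_perm_sine = if (is.null(n_perm_sine)) defaults$n_perm_sine
                       else as.integer(n_perm_sine),
         sine_freq_step_hz = sine_freq_step_hz,
         seed = as.integer(seed),
         combined_detrend = match.arg(combined_detrend)),
    class = "analysis_config"
  )
}

# run the PLS branch (spectra -> PLS -> both null tests -> Rayleigh at the
# peak) on a set of detrended courses
.pls_branch <- function(det, scfg, band_hz, n_perm, n_surr, seed) {
  R <- residual_matrix(det)
  spectra <- lapply(det, compute_spectrum, cfg = scfg)
  pls <- phase_locked_sum(spectra)
  peak <- find_peak(pls, band_hz)
  shuffle <- shuffle_null_test(det, scfg, band_hz, n_perm, seed = seed)
  ar1 <- ar1_surrogate_test(det, scfg, band_hz, n_surr, seed = seed + 1L)
  phases <- Arg(coeff_at_bin(R, scfg$n_padded, peak$index))
  list(detrended = det, trend_fits = attr(det, "trend_fits"),
       spectra = spectra, pls = pls, peak = peak,
       shuffle = shuffle, ar1 = ar1, rayleigh = rayleigh_test(phases))
}

#' Run the full behavioral-oscillation analysis
#'
#' Executes the complete pipeline on a trial table: per-participant
#' accuracy and the one-sided paired t-test between conditions; for the
#' combined data and each condition separately, exponential detrending,
#' zero-padded spectra, the group PLS with both the SOA-shuffle and
#' AR(1)-surrogate corrected p-values, and the Rayleigh test at the peak;
#' the group sinusoidal fit with its permutation p-value and the
#' sliding-window fit decay; the bootstrap peak-frequency comparison
#' between conditions (with a TOST equivalence test when the comparison is
#' not significant, and a paired amplitude t-test when it finds no
#' frequency difference); and the ITC/PLD contrast at the combined peak.
#' All randomness derives from `config$seed`, so the same inputs and seed
#' reproduce the report exactly.
#'
#' @param trials A `"trial_table"`.
#' @param config An [analysis_config()].
#' @param design The [rsvp_design()] describing the data.
#' @return An object of class `"study_report"`.
#' @export
run_full_analysis <- function(trials, config = analysis_config(),
                              design = rsvp_design()) {
  scfg <- spectral_config(fs_hz = 1000 / design$frame_ms,
                          band_hz = config$band_hz,
                          full_range_hz = config$full_range_hz)
  conds <- design$conditions
  seed <- config$seed

  # behavioural accuracy and the condition contrast
  acc_by_cond <- lapply(stats::setNames(conds, conds), function(cc) {
    courses <- aggregate_accuracy(trials, cc, 2)
    vapply(courses, function(cr) mean(cr$accuracy), numeric(1L))
  })
  one_target_acc <- aggregate_accuracy(trials, NULL, 1)
  paired_t <- if (length(conds) == 2L) {
    paired_one_sided_t(acc_by_cond[[1L]], acc_by_cond[[2L]])
  } else NULL

  # combined analysis: pooled-then-detrend by default; alternatively the
  # mean of per-condition detrended residuals
  combined_det <- if (config$combined_detrend == "pooled") {
    detrend_cohort(aggregate_accuracy(trials, NULL, 2))
  } else {
    per_cond_det <- lapply(conds, function(cc) {
      detrend_cohort(aggregate_accuracy(trials, cc, 2))
    })
    lapply(seq_along(per_cond_det[[1L]]), function(i) {
      ds <- lapply(per_cond_det, `[[`, i)
      new_detrended_course(ds[[1L]]$participant_id, "all", ds[[1L]]$soa_ms,
                           rowMeans(vapply(ds, `[[`,
                                           numeric(length(ds[[1L]]$soa_ms)),
                                           "residual")))
    })
  }
  combined <- .pls_branch(combined_det, scfg, config$band_hz,
                          config$n_perm, config$n_surr, seed)

  # sinusoidal fitting on the group-average detrended course
  group_course <- average_courses(combined$detrended)
  sine_grid <- seq(config$band_hz[1L], config$band_hz[2L],
                   by = config$sine_freq_step_hz)
  sine <- fit_sinusoid(group_course, sine_grid)
  sine$p_perm <- as.numeric(sinusoid_permutation_p(group_course, sine_grid,
                                                   config$n_perm_sine,
                                                   seed = seed + 2L))
  sliding <- sliding_window_fit(
    group_course, sine,
    ar1_surrogate_courses(group_course, config$n_surr_slide,
                          seed = seed + 3L)
  )

  # per-condition branches and comparisons
  per_condition <- lapply(stats::setNames(conds, conds), function(cc) {
    .pls_branch(detrend_cohort(aggregate_accuracy(trials, cc, 2)), scfg,
                config$band_hz, config$n_perm, config$n_surr,
                seed + 10L + match(cc, conds))
  })
  freq_comparison <- tost <- amp_t <- pld <- NULL
  if (length(conds) == 2L) {
    freq_comparison <- bootstrap_peak_comparison(
      per_condition[[1L]]$detrended, per_condition[[2L]]$detrended,
      scfg, config$band_hz, config$n_boot, seed = seed + 20L)
    if (!freq_comparison$significant) {
      tost <- tost_equivalence(freq_comparison)
      # no frequency difference: compare modulation ranges at the peak
      amp_at_peak <- lapply(per_condition, function(br) {
        vapply(br$spectra, function(s) {
          amplitude_to_variance(s$amplitude[combined$peak$index],
                                s$n_samples, s$n_padded)
        }, numeric(1L))
      })
      amp_t <- paired_one_sided_t(amp_at_peak[[1L]], amp_at_peak[[2L]])
    }
    pld <- itc_pld_test(trials, combined$peak$freq_hz, conditions = conds,
                        cfg = scfg, n_perm = config$n_perm,
                        seed = seed + 30L)
  }

  structure(
    list(design = design, config = config, spectral_config = scfg,
         accuracy_by_condition = acc_by_cond,
         one_target_accuracy = one_target_acc,
         paired_t = paired_t,
         combined = combined,
         sinusoid = sine, sliding = sliding,
         per_condition = per_condition,
         freq_comparison = freq_comparison, tost = tost,
         amplitude_t = amp_t, pld = pld,
         variance_explained = amplitude_to_variance(
           mean(vapply(combined$spectra, function(s)
             s$amplitude[combined$peak$index], numeric(1L))),
           combined$spectra[[1L]]$n_samples,
           combined$spectra[[1L]]$n_padded),
         version = as.character(utils::packageVersion("behavosc"))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("==== Behavioral-oscillation study report ====\n")
  cat(sprintf("%d participants, %d SOA levels, seed %d (%s profile)\n",
              x$combined$pls$n, x$design$n_soa_levels, x$config$seed,
              x$config$profile))
  if (!is.null(x$paired_t)) {
    cn <- names(x$accuracy_by_condition)
    cat(sprintf("\nAccuracy: %s %.2f%% vs %s %.2f%%; one-sided paired t(%d) = %.2f, p = %.3g\n",
                cn[1L], 100 * mean(x$accuracy_by_condition[[1L]]),
                cn[2L], 100 * mean(x$accuracy_by_condition[[2L]]),
                x$paired_t$df, x$paired_t$t, x$paired_t$p))
  }
  cat("\n-- Combined conditions --\n")
  print(x$combined$shuffle)
  cat(sprintf("  AR(1)-surrogate corrected p = %.4g\n", x$combined$ar1$p))
  print(x$combined$rayleigh)
  cat(sprintf("  peak-to-peak modulation explained: %.2f%%\n",
              100 * x$variance_explained))
  print(x$sinusoid)
  print(x$sliding)
  for (cc in names(x$per_condition)) {
    br <- x$per_condition[[cc]]
    cat(sprintf("\n-- Condition %s --\n  peak %.2f Hz%s, shuffle p = %.4g, surrogate p = %.4g\n",
                cc, br$peak$freq_hz, if (br$peak$edge) " [band edge]" else "",
                br$shuffle$p, br$ar1$p))
  }
  if (!is.null(x$freq_comparison)) { cat("\n"); print(x$freq_comparison) }
  if (!is.null(x$tost)) print(x$tost)
  if (!is.null(x$amplitude_t)) {
    cat(sprintf("Peak modulation range, one-sided paired t(%d) = %.2f, p = %.3g\n",
                x$amplitude_t$df, x$amplitude_t$t, x$amplitude_t$p))
  }
  if (!is.null(x$pld)) print(x$pld)
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  x <- object
  out <- list(
    n_participants = x$combined$pls$n,
    peak_freq_hz = x$combined$peak$freq_hz,
    peak_pls = x$combined$peak$value,
    peak_edge = x$combined$peak$edge,
    p_shuffle = x$combined$shuffle$p,
    p_ar1 = x$combined$ar1$p,
    rayleigh_z = x$combined$rayleigh$z,
    rayleigh_p = x$combined$rayleigh$p,
    variance_explained = x$variance_explained,
    sine_freq_hz = x$sinusoid$freq_hz,
    sine_adj_r2 = x$sinusoid$adj_r2,
    sine_p_perm = x$sinusoid$p_perm
  )
  if (!is.null(x$paired_t)) {
    out$accuracy_t <- x$paired_t$t
    out$accuracy_p <- x$paired_t$p
  }
  if (!is.null(x$freq_comparison)) out$freq_z <- x$freq_comparison$z
  if (!is.null(x$pld)) { out$pld <- x$pld$pld; out$pld_p <- x$pld$p }
  structure(out, class = "summary.study_report")
}

#' @export
print.summary.study_report <- function(x, ...) {
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("%-20s %s\n", nm, format(v[[nm]])))
  invisible(x)
}

#' Write a study report to a directory
#'
#' Writes `report.txt` (human-readable), `pls_curves.csv` (frequency, PLS
#' and the two 95th-percentile null curves for the combined analysis),
#' `sliding_fit.csv`, the resolved configuration as `config.txt`, and a
#' machine-readable `summary.json` (when the jsonlite package is
#' available).
#'
#' @param report A `"study_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  curves <- data.frame(
    freq_hz = report$combined$pls$freqs_hz,
    pls = report$combined$pls$pls,
    q95_shuffle = report$combined$shuffle$per_freq_q95,
    q95_ar1 = report$combined$ar1$per_freq_q95
  )
  utils::write.csv(curves, file.path(dir, "pls_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(center_ms = report$sliding$centers_ms,
               r2 = report$sliding$r2_per_center,
               significant = report$sliding$significant),
    file.path(dir, "sliding_fit.csv"), row.names = FALSE)
  cfg <- report$config
  writeLines(c(
    sprintf("profile=%s", cfg$profile),
    sprintf("band_hz=%g,%g", cfg$band_hz[1L], cfg$band_hz[2L]),
    sprintf("n_perm=%d", cfg$n_perm),
    sprintf("n_surr=%d", cfg$n_surr),
    sprintf("n_boot=%d", cfg$n_boot),
    sprintf("n_surr_slide=%d", cfg$n_surr_slide),
    sprintf("n_perm_sine=%d", cfg$n_perm_sine),
    sprintf("sine_freq_step_hz=%g", cfg$sine_freq_step_hz),
    sprintf("combined_detrend=%s", cfg$combined_detrend),
    sprintf("seed=%d", cfg$seed),
    sprintf("version=%s", report$version)
  ), file.path(dir, "config.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(summary(report)), file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a plain-text key=value configuration file
#'
#' Parses `key=value` lines (comments start with `#`) into an
#' [analysis_config()]. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return An `"analysis_config"`.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  known <- c("profile", "band_hz", "n_perm", "n_surr", "n_boot",
             "n_surr_slide", "n_perm_sine", "sine_freq_step_hz", "seed",
             "combined_detrend")
  if (any(!keys %in% known)) {
    stopf("unknown config key '%s'", keys[!keys %in% known][1L])
  }
  get_v <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  band <- get_v("band_hz")
  analysis_config(
    profile = get_v("profile", "full"),
    band_hz = if (is.null(band)) c(3, 13) else as.numeric(strsplit(band, ",")[[1L]]),
    n_perm = get_v("n_perm"), n_surr = get_v("n_surr"),
    n_boot = get_v("n_boot"), n_surr_slide = get_v("n_surr_slide"),
    n_perm_sine = get_v("n_perm_sine"),
    sine_freq_step_hz = as.numeric(get_v("sine_freq_step_hz", 0.01)),
    seed = as.integer(get_v("seed", 1L)),
    combined_detrend = get_v("combined_detrend", "pooled")
  )
}
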