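#' Spectral configuration for the accuracy time course
#'
#' Fixes the effective sampling rate of the SOA grid, the zero-padding
#' target resolution, and the frequency bands analysed. With the default
#' 30 Hz frame rate and 0.1 Hz resolution the padded length is
#' `M = round(fs / df) = 300` samples.
#'
#' @param fs_hz Effective sampling rate in Hz (one sample per stimulus
#'   frame; default 30).
#' @param freq_resolution_hz Frequency bin spacing after zero padding
#'   (default 0.1 Hz).
#' @param band_hz Closed band of interest in Hz (default `c(3, 13)`, the
#'   theta-alpha range).
#' @param full_range_hz Full reporting range, bounded above by the Nyquist
#'   frequency (default `c(0, 15)`).
#' @return An object of class `"spectral_config"` with the padded length
#'   `n_padded`.
#' @export
spectral_config <- function(fs_hz = 30, freq_resolution_hz = 0.1,
                            band_hz = c(3, 13), full_range_hz = c(0, fs_hz / 2)) {
  if (freq_resolution_hz <= 0) stopf("freq_resolution_hz must be positive")
  if (full_range_hz[2L] > fs_hz / 2 + 1e-9) {
    stopf("full_range_hz exceeds the Nyquist frequency %g Hz", fs_hz / 2)
  }
  M <- as.integer(round(fs_hz / freq_resolution_hz))
  structure(
    list(fs_hz = fs_hz, freq_resolution_hz = freq_resolution_hz,
         band_hz = band_hz, full_range_hz = full_range_hz, n_padded = M),
    class = "spectral_config"
  )
}

# frequency grid of the padded transform, DC..Nyquist
.freq_grid <- function(cfg) {
  (0:(cfg$n_padded %/% 2L)) * cfg$fs_hz / cfg$n_padded
}

#' Zero-padded amplitude/phase spectrum of a detrended course
#'
#' Computes the discrete Fourier transform of the `N` residuals appended
#' with `M - N` zeros, where `M` is the padded length set by the target
#' frequency resolution. Amplitudes use the fixed normalisation
#' `A = 2 |X| / M`, applied uniformly across bins; no window or further
#' demeaning is applied (residuals are near zero mean by construction).
#' Zero padding refines the bin spacing without altering the underlying
#' discrete-time Fourier transform, but spreads a fixed-length signal's
#' energy over `M` bins: a noiseless sinusoid of half-amplitude `A/2`
#' observed for `N` samples yields a peak of about `(A/2) N / M` under this
#' normalisation (hence the `2M/N` recovery factor of
#' [amplitude_to_variance()]).
#'
#' @param detrended A `"detrended_course"` on an equally spaced SOA grid.
#' @param cfg A [spectral_config()].
#' @return An object of class `"course_spectrum"`: `freqs_hz` (DC to
#'   Nyquist), complex `coeff`, `amplitude`, `phase` (radians in
#'   `(-pi, pi]`), and the lengths `n_samples`, `n_padded`.
#' @examples
#' cal <- make_calibration_course(4.6, 0.5)
#' sp <- compute_spectrum(cal, spectral_config())
#' sp$amplitude[sp$freqs_hz == 4.6]  # ~0.0167
#' @export
compute_spectrum <- function(detrended, cfg = spectral_config()) {
  stopifnot(inherits(detrended, "detrended_course"),
            inherits(cfg, "spectral_config"))
  x <- detrended$residual
  N <- length(x)
  if (N < 2L) stopf("need at least 2 samples")
  if (!is_equally_spaced(detrended$soa_ms)) {
    stopf("SOA grid is not equally spaced; the FFT requires uniform sampling")
  }
  M <- cfg$n_padded
  if (M < N) stopf("padded length %d is shorter than the series (%d)", M, N)
  X <- stats::fft(c(x, rep(0, M - N)))
  half <- X[seq_len(M %/% 2L + 1L)]
  structure(
    list(participant_id = detrended$participant_id,
         condition = detrended$condition,
         freqs_hz = .freq_grid(cfg),
         coeff = half,
         amplitude = 2 * Mod(half) / M,
         phase = Arg(half),
         n_samples = N, n_padded = M),
    class = "course_spectrum"
  )
}

#' @export
print.course_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: participant %s (%d samples padded to %d, %.3g Hz bins)\n",
              x$participant_id, x$n_samples, x$n_padded,
              x$freqs_hz[2L] - x$freqs_hz[1L]))
  invisible(x)
}

#' Group phase-locked sum (PLS)
#'
#' The PLS at frequency `f` is the modulus of the across-participant mean
#' of the normalised complex spectra,
#' \deqn{PLS_f = \left| \frac{1}{n} \sum_k A_{f,k} e^{i \theta_{f,k}} \right|,}
#' which is large only when the individual oscillations agree in phase
#' across participants: incoherent phases cancel even when individual
#' amplitudes are large. By the triangle inequality
#' `0 <= PLS_f <= mean_k A_{f,k}`.
#'
#' @param spectra A list of `"course_spectrum"` objects on a common
#'   frequency grid.
#' @return An object of class `"pls_curve"` with `freqs_hz`, `pls` and the
#'   participant count `n`.
#' @export
phase_locked_sum <- function(spectra) {
  if (length(spectra) < 1L) stopf("need at least one spectrum")
  freqs <- spectra[[1L]]$freqs_hz
  for (s in spectra) {
    stopifnot(inherits(s, "course_spectrum"))
    if (length(s$freqs_hz) != length(freqs) ||
        max(abs(s$freqs_hz - freqs)) > 1e-9) {
      stopf("spectra are not on a common frequency grid")
    }
  }
  Z <- vapply(spectra, function(s) s$amplitude * exp(1i * s$phase),
              complex(length(freqs)))
  Z <- matrix(Z, nrow = length(freqs))
  structure(
    list(freqs_hz = freqs, pls = Mod(rowMeans(Z)), n = length(spectra)),
    class = "pls_curve"
  )
}

#' @export
print.pls_curve <- function(x, ...) {
  pk <- find_peak(x, band_hz = range(x$freqs_hz))
  cat(sprintf("Phase-locked sum over %d participants; global max %.4g at %.2f Hz\n",
              x$n, pk$value, pk$freq_hz))
  invisible(x)
}

#' @export
plot.pls_curve <- function(x, band_hz = NULL, ...) {
  graphics::plot(x$freqs_hz, x$pls, type = "l", xlab = "Frequency (Hz)",
                 ylab = "PLS amplitude (a.u.)", ...)
  if (!is.null(band_hz)) graphics::abline(v = band_hz, lty = 3)
  invisible(x)
}

#' Locate the peak of a spectrum or PLS curve within a band
#'
#' Returns the frequency of the maximum value within the closed band. Ties
#' are broken toward the lower frequency. When the argmax sits on a band
#' edge the `edge` flag is set: an edge peak suggests the true peak may lie
#' outside the analysed band.
#'
#' @param x A `"pls_curve"` or `"course_spectrum"`.
#' @param band_hz Closed frequency band `c(lo, hi)` within the grid.
#' @return A list with `freq_hz`, `value`, `edge` and the grid `index`.
#' @export
find_peak <- function(x, band_hz = c(3, 13)) {
  if (inherits(x, "pls_curve")) {
    freqs <- x$freqs_hz; vals <- x$pls
  } else if (inherits(x, "course_spectrum")) {
    freqs <- x$freqs_hz; vals <- x$amplitude
  } else {
    stopf("x must be a pls_curve or course_spectrum")
  }
  idx <- which(freqs >= band_hz[1L] - 1e-9 & freqs <= band_hz[2L] + 1e-9)
  if (length(idx) == 0L) stopf("band [%g, %g] Hz contains no frequency bins",
                               band_hz[1L], band_hz[2L])
  i <- idx[which.max(vals[idx])]    # which.max: first max = lowest frequency
  list(freq_hz = freqs[i], value = vals[i],
       edge = i == idx[1L] || i == idx[length(idx)],
       index = i)
}

#' Convert a spectral peak amplitude to a peak-to-peak modulation range
#'
#' Inverts the padding loss of [compute_spectrum()]: a sinusoid with
#' peak-to-peak range `r` observed for `N` samples and padded to `M`
#' produces a peak amplitude of about `r * N / (2M)`, so the range is
#' recovered as `amplitude * 2M / N`. For the default 20-point course
#' padded to 300 the factor is exactly 30. "Variance" follows the field's
#' loose usage for the peak-to-peak range of the modulation (a range of
#' 0.5 means accuracy swings -25% to +25% around trend).
#'
#' @param amplitude Peak amplitude(s) in the `2|X|/M` normalisation.
#' @param n_samples Unpadded series length `N`.
#' @param n_padded Padded length `M` (>= `N`).
#' @return The peak-to-peak modulation range, in accuracy units.
#' @examples
#' amplitude_to_variance(0.0167, 20, 300)  # ~0.5
#' @export
amplitude_to_variance <- function(amplitude, n_samples = 20, n_padded = 300) {
  if (n_padded < n_samples) stopf("n_padded must be >= n_samples")
  amplitude * 2 * n_padded / n_samples
}

# ---- fast internal kernels used by resampling loops ----

# PLS curve (DC..Nyquist) from an N x n residual matrix, padded to M
pls_from_matrix <- function(R, M) {
  N <- nrow(R); n <- ncol(R)
  Z <- stats::mvfft(rbind(R, matrix(0, M - N, n)))
  (2 / (M * n)) * Mod(rowSums(Z[seq_len(M %/% 2L + 1L), , drop = FALSE]))
}

# per-participant normalised complex coefficients at one padded bin
coeff_at_bin <- function(R, M, bin) {
  N <- nrow(R)
  Z <- stats::mvfft(rbind(R, matrix(0, M - N, ncol(R))))
  2 * Z[bin, ] / M
}
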