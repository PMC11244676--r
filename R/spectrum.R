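#' Discrete Fourier spectrum of HU samples along a contour
#'
#' Computes the unnormalized DFT \eqn{X_k = \sum_t h_t e^{-2\pi i k t / N}}
#' of the HU sequence and returns the amplitudes \eqn{|X_k|} with their
#' frequencies in cycles per sample. For real input the spectrum is
#' conjugate-symmetric, \eqn{|X_k| = |X_{N-k}|}.
#'
#' @param trace a [extract_metal_contour()] result, or a numeric vector of
#'   at least 8 finite samples.
#' @return An object of class `frequency_spectrum`: `amplitudes` (length N)
#'   and `frequencies` (`(0:(N-1))/N`).
#' @export
compute_spectrum <- function(trace) {
  h <- if (inherits(trace, "contour_trace")) trace$hu_samples else as.numeric(trace)
  if (length(h) < 8L) stop("need at least 8 samples")
  if (any(!is.finite(h))) stop("non-finite HU sample in contour trace")
  X <- stats::fft(h)
  n <- length(h)
  structure(
    list(amplitudes = Mod(X), frequencies = (seq_len(n) - 1) / n),
    class = "frequency_spectrum"
  )
}

#' Low-frequency streak amplitude over three sequential slices
#'
#' For each of the slices `center_slice - 1`, `center_slice`,
#' `center_slice + 1`, a contour surrounding the metal is delineated
#' ([extract_metal_contour()], re-delineated per slice), its HU samples are
#' Fourier transformed, and the per-slice streak statistic is the summed
#' amplitude of bins 1 and 2, \eqn{|X_1| + |X_2|}. Bright/dark streaks
#' radiating from metal modulate the contour at low angular order, so energy
#' concentrates in these bins; with the default 141 samples bin 2 sits at
#' frequency 2/141 ~ 0.0142 cycles/sample. The DC bin is excluded, making
#' the statistic invariant to a constant HU offset and to the contour's
#' starting point.
#'
#' @inheritParams extract_metal_contour
#' @param center_slice 0-based index of the middle slice; its two neighbours
#'   must also be valid, metal-bearing slices.
#' @return An object of class `streak_result`: `amplitude_low_freq` (mean of
#'   the three per-slice values), `cv` (coefficient of variation, percent,
#'   sample SD / mean x 100), and `per_slice` (length 3).
#' @export
compute_amplitude_low_freq <- function(volume, center_slice,
                                       metal_threshold = 800,
                                       offset_voxels = 3, n_points = 141) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  slices <- center_slice + (-1:1)
  if (slices[1] < 0 || slices[3] > d[1] - 1L)
    stop("center_slice must leave one valid slice on each side")
  per_slice <- vapply(slices, function(s) {
    tr <- extract_metal_contour(volume, s, metal_threshold = metal_threshold,
                                offset_voxels = offset_voxels,
                                n_points = n_points)
    amp <- compute_spectrum(tr)$amplitudes
    amp[2] + amp[3]
  }, numeric(1))
  m <- mean(per_slice)
  structure(
    list(
      amplitude_low_freq = m,
      cv = if (m > 0) 100 * stats::sd(per_slice) / m else 0,
      per_slice = per_slice
    ),
    class = "streak_result"
  )
}

#' @export
print.streak_result <- function(x, ...) {
  cat(sprintf("<streak_result> AmplitudeLowFreq = %.1f (CV %.1f%%; slices: %s)\n",
              x$amplitude_low_freq, x$cv,
              paste(format(x$per_slice, digits = 5), collapse = ", ")))
  invisible(x)
}
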