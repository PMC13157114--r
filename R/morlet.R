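#' Complex Morlet wavelet kernel
#'
#' The kernel is a complex exponential under a Gaussian envelope with
#' time-domain standard deviation `cycles / (2 * pi * freq)` seconds,
#' truncated at 3.5 standard deviations. The accompanying normalization
#' constant converts the convolution modulus into sinusoid amplitude: a
#' stationary unit-amplitude sinusoid at `freq` yields an envelope of 1.0
#' away from edges, making amplitudes comparable across frequencies even
#' with frequency-dependent cycle counts.
#'
#' @param freq analysis frequency in Hz.
#' @param sfreq sampling rate in Hz.
#' @param cycles number of wavelet cycles (default `freq / 2`).
#' @return list with `kernel` (complex vector), `norm` (amplitude
#'   normalization), and `half_width_s` (effective half width in seconds,
#'   the edge-flagging radius).
#' @export
morlet_kernel <- function(freq, sfreq, cycles = freq / 2) {
  stopifnot(freq > 0, sfreq > 0)
  if (freq >= sfreq / 2) stop("analysis frequency must be below Nyquist")
  if (cycles < 1) stop("cycles must be >= 1")
  sigma_t <- cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sigma_t * sfreq)
  tt <- seq(-half, half) / sfreq
  env <- exp(-tt^2 / (2 * sigma_t^2))
  list(
    kernel = env * exp(1i * 2 * pi * freq * tt),
    norm = sum(env) / 2,
    half_width_s = half / sfreq
  )
}

# FFT-based "same" convolution of a real vector with a complex kernel.
#' @keywords internal
convolve_same <- function(x, kernel) {
  nk <- length(kernel)
  nx <- length(x)
  n <- stats::nextn(nx + nk - 1, 2)
  X <- stats::fft(c(x, rep(0, n - nx)))
  K <- stats::fft(c(kernel, rep(0, n - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / n
  half <- (nk - 1) / 2
  full[(half + 1):(half + nx)]
}

#' Morlet amplitude envelope of a single time series
#'
#' Returns the instantaneous amplitude (in the units of `x`, typically
#' microvolts) of `x` at `freq`. Edges are handled by mirror padding with
#' one kernel length, which keeps stationary oscillations unbiased up to a
#' phase-discontinuity glitch confined to within one wavelet half width of
#' the segment edges; use `morlet_edge_mask()` to flag those samples.
#'
#' @inheritParams morlet_kernel
#' @param x numeric vector.
#' @return numeric vector of amplitudes, same length as `x`.
#' @export
morlet_envelope <- function(x, freq, sfreq, cycles = freq / 2) {
  mk <- morlet_kernel(freq, sfreq, cycles)
  npad <- min(length(x) - 1, length(mk$kernel))
  xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(length(x) - npad):(length(x) - 1)]))
  env <- Mod(convolve_same(xp, mk$kernel)) / mk$norm
  env[(npad + 1):(npad + length(x))]
}

#' Samples within one wavelet half width of a segment edge
#'
#' @inheritParams morlet_kernel
#' @param n_samples segment length.
#' @return logical vector, `TRUE` where the envelope is edge-contaminated.
#' @export
morlet_edge_mask <- function(n_samples, freq, sfreq, cycles = freq / 2) {
  half <- ceiling(morlet_kernel(freq, sfreq, cycles)$half_width_s * sfreq)
  idx <- seq_len(n_samples)
  idx <= half | idx > n_samples - half
}
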