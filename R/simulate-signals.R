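#' Steady-state flicker waveform
#'
#' Pure sinusoid at the stimulus flicker frequency, the signal model of a
#' frequency-tagged steady-state visual evoked response.
#'
#' @param t time axis, seconds.
#' @param freq flicker frequency, Hz; must be below Nyquist of the axis.
#' @param amplitude peak amplitude, uV.
#' @param phase phase offset, radians.
#' @return numeric waveform, uV.
#' @export
ssvep_waveform <- function(t, freq, amplitude, phase = 0) {
  stopifnot(amplitude >= 0)
  if (length(t) > 1) {
    sfreq <- 1 / stats::median(diff(t))
    if (freq >= sfreq / 2) stop("flicker frequency must be below Nyquist")
  }
  amplitude * sin(2 * pi * freq * t + phase)
}

# Cosine-tapered plateau: 1 on [center - flat, center + flat], cosine ramp
# to 0 over `ramp`, 0 beyond. Plateau height 1 means both the windowed mean
# and the windowed peak of an amplitude-scaled bump recover the amplitude.
#' @keywords internal
taper_bump <- function(t_ms, center_ms, flat_halfwidth_ms, ramp_ms) {
  d <- abs(t_ms - center_ms)
  out <- numeric(length(d))
  out[d <= flat_halfwidth_ms] <- 1
  ramp <- d > flat_halfwidth_ms & d < flat_halfwidth_ms + ramp_ms
  x <- (d[ramp] - flat_halfwidth_ms) / ramp_ms
  out[ramp] <- cos(pi * x / 2)^2
  out
}

#' ERP template waveform for one expression
#'
#' Sum of cosine-tapered plateau bumps, one per component, with
#' per-expression amplitude offsets, projected onto the montage channels via
#' each component's cluster and hemisphere weights.
#'
#' @param t_ms epoch time axis, ms (0 = stimulus onset).
#' @param channels channel labels of the output rows.
#' @param expression one of "angry", "happy", "neutral".
#' @param erp_params component list as in [default_erp_params()].
#' @param gain global multiplicative gain (group/participant scaling).
#' @return matrix channels x time, uV.
#' @export
erp_template <- function(t_ms, channels, expression,
                         erp_params = default_erp_params(), gain = 1) {
  out <- matrix(0, length(channels), length(t_ms),
                dimnames = list(channels, NULL))
  hemi <- channel_hemisphere(channels)
  for (comp in erp_params) {
    stopifnot(comp$flat_halfwidth_ms > 0, comp$ramp_ms > 0)
    amp <- (comp$base_uv + comp$offsets_uv[[expression]]) * gain
    bump <- amp * taper_bump(t_ms, comp$center_ms, comp$flat_halfwidth_ms,
                             comp$ramp_ms)
    for (ch in intersect(comp$cluster, channels)) {
      w <- switch(channel_hemisphere(ch),
                  left = comp$hemi_weights[["left"]],
                  right = comp$hemi_weights[["right"]],
                  midline = mean(comp$hemi_weights))
      out[ch, ] <- out[ch, ] + w * bump
    }
  }
  out
}

#' Bi-exponential skin conductance response
#'
#' `r(t) = a * (exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise))` for
#' `t >= t0` and zero before, rescaled so the maximum equals `amplitude`.
#'
#' @param t time axis, seconds.
#' @param onset response onset `t0`, seconds.
#' @param amplitude peak amplitude, uS.
#' @param tau_rise rise time constant, seconds.
#' @param tau_decay decay time constant, seconds; must exceed `tau_rise`.
#' @return numeric waveform, uS.
#' @export
scr_curve <- function(t, onset, amplitude, tau_rise = 0.75, tau_decay = 6) {
  if (tau_decay <= tau_rise || tau_rise <= 0) {
    stop("scr_curve requires tau_decay > tau_rise > 0")
  }
  stopifnot(amplitude >= 0)
  dt <- t - onset
  shape <- ifelse(dt >= 0, exp(-dt / tau_decay) - exp(-dt / tau_rise), 0)
  # analytic maximum of the bi-exponential shape
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  if (peak <= 0) return(shape * 0)
  amplitude * shape / peak
}

#' 1/f background noise
#'
#' Spectrally shaped white noise: the amplitude spectrum of Gaussian white
#' noise is multiplied by `f^(-exponent/2)` (power falls as `1/f^exponent`)
#' and the result rescaled to the requested standard deviation.
#'
#' @param n number of samples.
#' @param sfreq sampling rate, Hz.
#' @param sd target standard deviation, uV.
#' @param exponent spectral exponent of the power spectrum (default 1).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sfreq, sd = 1, exponent = 1) {
  if (sd == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5)) # smooth FFT length; truncate afterwards
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- seq(0, m - 1) / m * sfreq
  f <- pmin(f, sfreq - f)
  shape <- c(0, f[-1]^(-exponent / 2)) # drop DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE) / m)[seq_len(n)]
  sd * (x - mean(x)) / stats::sd(x)
}
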