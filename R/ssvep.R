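#' Default analysis frequencies for the tagged-attention task
#'
#' Ten logarithmically spaced frequencies spanning 1-40 Hz, with the two tag
#' frequencies appended explicitly (the log grid does not land on them, and
#' the bias scores are defined at the tags).
#'
#' @param tags flicker frequencies, Hz.
#' @return sorted numeric vector of frequencies.
#' @export
ssvep_analysis_freqs <- function(tags = c(12, 15)) {
  sort(unique(c(10^seq(log10(1), log10(40), length.out = 10), tags)))
}

#' Occipital/parieto-occipital channel cluster for tagged amplitudes
#' @return character vector of channel labels.
#' @export
ssvep_cluster <- function() c("O1", "O2", "Oz", "PO7", "PO8", "P9", "P10")

#' Analysis windows for attentional bias scores
#' @return named list of (start, end) ms pairs: four interval windows plus
#'   the global window.
#' @export
default_abs_windows <- function() {
  list("100-500" = c(100, 500), "500-1000" = c(500, 1000),
       "1000-2000" = c(1000, 2000), "2000-3000" = c(2000, 3000),
       "100-3000" = c(100, 3000))
}

#' Single-sided FFT amplitude at given frequencies
#'
#' Computes, per channel, the single-sided amplitude spectrum of the
#' epoch-window samples (half-open window, so a 0-3000 ms window at 512 Hz
#' uses exactly 1536 samples) and reads it at the bins nearest the requested
#' frequencies. A unit-amplitude sinusoid at a bin frequency returns 1.0 uV.
#' Warns when a window does not hold an integer number of cycles of every
#' requested frequency (spectral leakage).
#'
#' @param ep an [epoch()] set.
#' @param freqs frequencies to read, Hz.
#' @param window_ms analysis window (start, end), ms, half-open.
#' @param trials trial indices to include (default all unrejected).
#' @return matrix frequencies x channels of amplitudes (uV), averaged over
#'   the included trials' amplitude spectra.
#' @export
fft_amplitude <- function(ep, freqs = c(12, 15), window_ms = c(0, 3000),
                          trials = which(!ep$rejected)) {
  sel <- ep$times_ms >= window_ms[1] & ep$times_ms < window_ms[2]
  if (!any(sel)) stop("window outside the epoch")
  n <- sum(sel)
  span_s <- n / ep$sfreq
  cyc <- freqs * span_s
  if (any(abs(cyc - round(cyc)) > 1e-6)) {
    warning("window does not hold an integer number of cycles at ",
            paste(freqs[abs(cyc - round(cyc)) > 1e-6], collapse = ", "),
            " Hz; expect spectral leakage")
  }
  bin_freqs <- seq(0, n - 1) / span_s
  bins <- vapply(freqs, function(f) which.min(abs(bin_freqs[1:(n %/% 2)] - f)),
                 integer(1))
  out <- matrix(0, length(freqs), length(ep$channels),
                dimnames = list(paste0(freqs, "Hz"), ep$channels))
  for (tr in trials) {
    seg <- ep$data[tr, , sel, drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    sp <- t(apply(seg, 1, function(x) 2 * Mod(stats::fft(x)) / n))
    out <- out + t(sp[, bins, drop = FALSE])
  }
  out / length(trials)
}

#' Morlet time-frequency amplitude of an epoch set
#'
#' Per-trial amplitude envelopes from complex Morlet wavelets with
#' `cycles = freq / 2`, normalized so a stationary unit-amplitude sinusoid
#' at an analysis frequency yields 1.0 away from epoch edges. Samples within
#' one wavelet half width of an epoch edge are flagged in `edge_mask`.
#'
#' @param ep an [epoch()] set.
#' @param freqs analysis frequencies, Hz.
#' @param channels channels to decompose (default all).
#' @param cycles_fun cycle count as a function of frequency.
#' @return object of class `tfr_amplitude`: `amplitude` array
#'   (trials x freqs x channels x times, uV), `freqs`, `channels`,
#'   `times_ms`, `edge_mask` (freqs x times).
#' @export
morlet_amplitude <- function(ep, freqs = ssvep_analysis_freqs(),
                             channels = ep$channels,
                             cycles_fun = function(f) f / 2) {
  stopifnot(all(channels %in% ep$channels))
  if (any(freqs >= ep$sfreq / 2)) stop("analysis frequency above Nyquist")
  freqs <- sort(freqs)
  ch_idx <- match(channels, ep$channels)
  n_t <- dim(ep$data)[1]
  n_s <- dim(ep$data)[3]
  amp <- array(NA_real_, c(n_t, length(freqs), length(channels), n_s))
  edge <- matrix(FALSE, length(freqs), n_s)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    edge[fi, ] <- morlet_edge_mask(n_s, f, ep$sfreq, cycles_fun(f))
    for (ci in seq_along(ch_idx)) {
      for (tr in seq_len(n_t)) {
        x <- ep$data[tr, ch_idx[ci], ]
        if (anyNA(x)) next
        amp[tr, fi, ci, ] <- morlet_envelope(x, f, ep$sfreq, cycles_fun(f))
      }
    }
  }
  structure(
    list(amplitude = amp, freqs = freqs, channels = channels,
         times_ms = ep$times_ms, edge_mask = edge, sfreq = ep$sfreq),
    class = "tfr_amplitude"
  )
}

#' Mean tagged amplitude per trial
#'
#' Averages the wavelet amplitude envelope at one tag frequency over the
#' channel cluster and time window, per trial.
#'
#' @param tfr a [morlet_amplitude()] result.
#' @param freq tag frequency, Hz (must be in `tfr$freqs`).
#' @param window_ms (start, end) ms.
#' @param channels channel subset (default the full cluster in the TFR).
#' @return numeric vector, one amplitude (uV) per trial.
#' @export
tagged_amplitude <- function(tfr, freq, window_ms = c(100, 3000),
                             channels = tfr$channels) {
  fi <- which(abs(tfr$freqs - freq) < 1e-9)
  if (length(fi) != 1) stop("frequency not in the TFR")
  ci <- match(channels, tfr$channels)
  if (anyNA(ci)) stop("channels not in the TFR")
  sel <- tfr$times_ms >= window_ms[1] & tfr$times_ms <= window_ms[2]
  apply(tfr$amplitude[, fi, ci, sel, drop = FALSE], 1, mean)
}

#' Attentional bias score
#'
#' Normalized amplitude difference `(a - b) / (a + b)` between the
#' higher-arousal and lower-arousal stimulus of a competing pair. Lies in
#' `[-1, 1]`, is antisymmetric under swapping the stimuli, and is positive
#' when attention (tagged amplitude) favours the higher-arousal face. A zero
#' total amplitude gives NA with a warning, never 0.
#'
#' @param amp_high amplitude of the higher-arousal stimulus, uV (>= 0).
#' @param amp_low amplitude of the lower-arousal stimulus, uV (>= 0).
#' @return dimensionless score(s) in `[-1, 1]`.
#' @export
abs_score <- function(amp_high, amp_low) {
  if (any(amp_high < 0, na.rm = TRUE) || any(amp_low < 0, na.rm = TRUE)) {
    stop("amplitudes must be nonnegative")
  }
  total <- amp_high + amp_low
  out <- ifelse(total > 0, (amp_high - amp_low) / total, NA_real_)
  if (any(total == 0, na.rm = TRUE)) {
    warning("zero total amplitude: bias score undefined, returning NA")
  }
  out
}

#' Attentional bias score table for one participant
#'
#' Runs the Morlet decomposition at the two tag frequencies over the
#' occipital cluster, keys each trial's two stimulus amplitudes by the
#' flicker frequency on the corresponding side, averages amplitudes within
#' condition cells (combination x side of the higher-arousal face) over
#' unrejected trials, and converts cell means to bias scores for the four
#' interval windows plus the global window.
#'
#' @param ep an [epoch()] set whose conditions carry `combination`,
#'   `side_high`, `freq_left`, `freq_right`.
#' @param participant,group identifiers copied into the output.
#' @param windows named list of (start, end) ms windows.
#' @param channels cluster channel labels.
#' @param sum_tags if `TRUE`, a stimulus's amplitude is the sum over both
#'   tag frequencies instead of its own tag only (alternative reading of
#'   cross-frequency summation; default off because the score is only
#'   identifiable per stimulus through its own tag).
#' @return data.frame `participant`, `group`, `combination`, `hemifield`,
#'   `window`, `abs`: one row per window x combination x hemifield.
#' @export
abs_table <- function(ep, participant = "p1", group = NA_character_,
                      windows = default_abs_windows(),
                      channels = ssvep_cluster(), sum_tags = FALSE) {
  cond <- ep$conditions
  need <- c("combination", "side_high", "freq_left", "freq_right")
  if (!all(need %in% names(cond))) stop("conditions lack ATB columns")
  keep <- !ep$rejected
  tags <- sort(unique(c(cond$freq_left, cond$freq_right)))
  tfr <- morlet_amplitude(ep, freqs = tags, channels = channels)
  rows <- list()
  for (wname in names(windows)) {
    win <- windows[[wname]]
    per_tag <- vapply(tags, function(f) tagged_amplitude(tfr, f, win),
                      numeric(dim(ep$data)[1]))
    colnames(per_tag) <- as.character(tags)
    freq_high <- ifelse(cond$side_high == "left", cond$freq_left,
                        cond$freq_right)
    freq_low <- ifelse(cond$side_high == "left", cond$freq_right,
                       cond$freq_left)
    amp_high <- per_tag[cbind(seq_len(nrow(cond)), match(freq_high, tags))]
    amp_low <- per_tag[cbind(seq_len(nrow(cond)), match(freq_low, tags))]
    if (sum_tags) {
      both <- rowSums(per_tag)
      amp_high <- both
      amp_low <- both
    }
    for (combo in unique(cond$combination)) {
      for (side in c("left", "right")) {
        cell <- keep & cond$combination == combo & cond$side_high == side
        rows[[length(rows) + 1]] <- data.frame(
          participant = participant, group = group, combination = combo,
          hemifield = side, window = wname,
          abs = if (any(cell)) {
            abs_score(mean(amp_high[cell]), mean(amp_low[cell]))
          } else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
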