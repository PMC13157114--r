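#' Frontal alpha event-related desynchronization
#'
#' Alpha power is the squared Morlet amplitude envelope (cycles = freq/2,
#' unit-sinusoid normalization), averaged over the band frequencies and the
#' frontal channels. Per trial, power is averaged within the baseline and
#' stimulus windows and log10-transformed; the ERD value is the mean over
#' trials of (log10 stimulus power - log10 baseline power). Negative values
#' denote desynchronization. For a pure envelope gain g applied to the alpha
#' oscillation in the stimulus window, the ERD value equals `2 * log10(g)`.
#'
#' The stimulus window starts at 200 ms and ends at 2800 ms to keep one
#' wavelet half width clear of the epoch edges; supplying epochs with extra
#' pre-stimulus padding (the pipeline uses 500 ms) removes residual edge
#' bias in the short baseline window.
#'
#' @param ep an [epoch()] set.
#' @param channels frontal channel labels.
#' @param band alpha band limits, Hz; analysis frequencies are the integer
#'   frequencies spanning the band.
#' @param baseline baseline window, ms.
#' @param stim stimulus window, ms.
#' @param participant,group identifiers copied into the output.
#' @param evoked if `TRUE`, power is computed on the trial-averaged signal
#'   (evoked) instead of per trial (induced, the default).
#' @return list of class `erd_result`: `erd_value`, `time_resolved`
#'   (data.frame `time_ms`, `log_power_rel`, the trial-mean log10 power
#'   relative to baseline), `band`, `channels`, `participant`, `group`.
#' @export
alpha_erd <- function(ep, channels = c("Fp1", "Fp2", "Fpz"),
                      band = c(8, 13), baseline = c(-200, 0),
                      stim = c(200, 2800), participant = "p1",
                      group = NA_character_, evoked = FALSE) {
  if (min(ep$times_ms) > baseline[1] || max(ep$times_ms) < stim[2]) {
    stop("epoch does not cover the baseline and stimulus windows")
  }
  freqs <- seq(ceiling(band[1]), floor(band[2]))
  keep <- which(!ep$rejected)
  if (length(keep) == 0) stop("no unrejected trials")
  if (evoked) {
    avg <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), mean)
    ep2 <- ep
    ep2$data <- array(avg, c(1, dim(avg)))
    ep2$rejected <- FALSE
    ep2$conditions <- ep$conditions[1, , drop = FALSE]
    ep <- ep2
    keep <- 1L
  }
  tfr <- morlet_amplitude(ep, freqs = freqs, channels = channels)
  # power: mean over band frequencies and channels, per trial and sample
  pw <- apply(tfr$amplitude[keep, , , , drop = FALSE]^2, c(1, 4), mean)
  b_sel <- ep$times_ms >= baseline[1] & ep$times_ms < baseline[2]
  s_sel <- ep$times_ms >= stim[1] & ep$times_ms <= stim[2]
  base_p <- rowMeans(pw[, b_sel, drop = FALSE])
  stim_p <- rowMeans(pw[, s_sel, drop = FALSE])
  if (any(base_p <= 0) || any(stim_p <= 0)) {
    warning("zero power in a window: ERD undefined")
    erd <- NA_real_
    curve <- rep(NA_real_, length(ep$times_ms))
  } else {
    erd <- mean(log10(stim_p) - log10(base_p))
    curve <- colMeans(log10(pw) - log10(base_p))
  }
  structure(
    list(erd_value = erd,
         time_resolved = data.frame(time_ms = ep$times_ms,
                                    log_power_rel = curve),
         band = band, channels = channels,
         participant = participant, group = group),
    class = "erd_result"
  )
}

#' @export
print.erd_result <- function(x, ...) {
  cat(sprintf("<erd_result> %s: %.3f (log10 power, %g-%g Hz at %s)\n",
              x$participant, x$erd_value, x$band[1], x$band[2],
              paste(x$channels, collapse = "/")))
  invisible(x)
}
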