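#' Band-pass filter a skin conductance trace before scoring
#'
#' Zero-phase 0.01-5 Hz band-pass (Butterworth magnitude response), the
#' conditioning applied to electrodermal data ahead of trough-to-peak
#' scoring; it suppresses measurement noise above the electrodermal band
#' and slow tonic drift.
#'
#' @param trace data.frame with `time_s`, `value_us`.
#' @param low,high band edges, Hz.
#' @return filtered trace, same shape.
#' @export
preprocess_scr <- function(trace, low = 0.01, high = 5) {
  fs <- 1 / stats::median(diff(trace[[1]]))
  out <- trace
  out[[2]] <- fft_zero_phase(trace[[2]], fs, low = low, high = high)
  out
}

#' Trough-to-peak skin conductance scoring for one trial
#'
#' The valley is the minimum of the trace within 1000-4000 ms after
#' stimulus onset and the peak the maximum within 1500-7500 ms, restricted
#' to times after the valley; ties break to the earliest sample. The
#' amplitude is peak minus valley. A response is valid only if the trace
#' covers the full 0-7500 ms post-onset span (otherwise `short_trial`), a
#' peak exists after the valley (`no_peak_after_valley`), and the amplitude
#' is at least 0.02 uS (responses below threshold are excluded;
#' amplitude >= 0.02 is valid).
#'
#' @param trace data.frame with columns `time_s` and `value_us`, or a
#'   two-column numeric matrix.
#' @param onset_s stimulus onset, seconds.
#' @param trial_id identifier copied into the output.
#' @param valley_window,peak_window ms after onset.
#' @param threshold_us minimum valid amplitude, uS.
#' @return one-row data.frame: `trial_id`, `valley_us`, `valley_ms`,
#'   `peak_us`, `peak_ms`, `amplitude_us`, `valid`, `exclusion_reason`
#'   (one of `none`, `below_threshold`, `no_peak_after_valley`,
#'   `short_trial`).
#' @export
score_scr <- function(trace, onset_s, trial_id = NA_integer_,
                      valley_window = c(1000, 4000),
                      peak_window = c(1500, 7500),
                      threshold_us = 0.02) {
  time_s <- trace[[1]]
  value <- trace[[2]]
  rel_ms <- (time_s - onset_s) * 1000
  empty <- function(reason) data.frame(
    trial_id = trial_id, valley_us = NA_real_, valley_ms = NA_real_,
    peak_us = NA_real_, peak_ms = NA_real_, amplitude_us = NA_real_,
    valid = FALSE, exclusion_reason = reason, stringsAsFactors = FALSE
  )
  if (max(rel_ms) < peak_window[2]) return(empty("short_trial"))
  v_sel <- which(rel_ms >= valley_window[1] & rel_ms <= valley_window[2])
  if (length(v_sel) == 0) return(empty("short_trial"))
  v_idx <- v_sel[which.min(value[v_sel])] # which.min takes the earliest tie
  p_sel <- which(rel_ms >= max(peak_window[1], rel_ms[v_idx]) &
                   rel_ms <= peak_window[2] & rel_ms > rel_ms[v_idx])
  if (length(p_sel) == 0) return(empty("no_peak_after_valley"))
  p_idx <- p_sel[which.max(value[p_sel])]
  amp <- value[p_idx] - value[v_idx]
  valid <- amp >= threshold_us
  data.frame(
    trial_id = trial_id, valley_us = value[v_idx], valley_ms = rel_ms[v_idx],
    peak_us = value[p_idx], peak_ms = rel_ms[p_idx], amplitude_us = amp,
    valid = valid,
    exclusion_reason = if (valid) "none" else "below_threshold",
    stringsAsFactors = FALSE
  )
}

#' Score every trial of a skin conductance trace
#'
#' @param trace as in [score_scr()].
#' @param onsets_s per-trial onsets, seconds.
#' @param trial_ids per-trial identifiers.
#' @return data.frame of per-trial scores.
#' @export
score_scr_trials <- function(trace, onsets_s,
                             trial_ids = seq_along(onsets_s)) {
  do.call(rbind, lapply(seq_along(onsets_s), function(i) {
    score_scr(trace, onsets_s[i], trial_ids[i])
  }))
}

#' Condition-level SCR means with the minimum-valid-trials inclusion rule
#'
#' A participant enters the SCR analysis only if every condition cell holds
#' at least `min_valid` valid responses; cell values are means over valid
#' trials. Raising `min_valid` can only remove participants.
#'
#' @param scores per-trial score table from [score_scr_trials()].
#' @param conditions data.frame with `trial_id` and a `condition` column.
#' @param condition_col name of the condition column.
#' @param min_valid minimum valid trials per cell (default 5).
#' @return list: `cells` (data.frame `condition`, `n_valid`, `mean_us`) and
#'   `included` (logical).
#' @export
participant_scr_cells <- function(scores, conditions,
                                  condition_col = "condition",
                                  min_valid = 5) {
  m <- merge(scores, conditions[, c("trial_id", condition_col)],
             by = "trial_id")
  cells <- do.call(rbind, lapply(split(m, m[[condition_col]]), function(d) {
    v <- d$valid
    data.frame(condition = d[[condition_col]][1], n_valid = sum(v),
               mean_us = if (any(v)) mean(d$amplitude_us[v]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  list(cells = cells, included = all(cells$n_valid >= min_valid))
}

#' Baseline-corrected heart-rate window means from an RR series
#'
#' Instantaneous heart rate (60000 / RR, beats per minute) is assigned to
#' each beat time, linearly interpolated onto a uniform grid, and averaged
#' within each analysis window relative to the stimulus onset; the mean over
#' the baseline window is subtracted.
#'
#' @param rr data.frame with `beat_time_ms` and `rr_ms`.
#' @param onset_ms stimulus onset, ms.
#' @param windows named list of (start, end) ms windows; defaults are the
#'   deceleration (0-1000), acceleration (1000-3000), recovery (3000-7500),
#'   and overall (0-7500) windows of the attention task.
#' @param baseline baseline window, ms relative to onset.
#' @param grid_hz interpolation grid rate.
#' @return data.frame `window`, `mean_hr_bpm` (baseline corrected); NA with
#'   a reason attribute when no beats cover a window.
#' @export
hr_windows <- function(rr, onset_ms,
                       windows = list("0-1000" = c(0, 1000),
                                      "1000-3000" = c(1000, 3000),
                                      "3000-7500" = c(3000, 7500),
                                      "0-7500" = c(0, 7500)),
                       baseline = c(-1000, 0), grid_hz = 10) {
  hr <- 60000 / rr$rr_ms
  t <- rr$beat_time_ms - onset_ms
  span <- range(c(baseline, unlist(windows)))
  if (min(t) > span[1] || max(t) < span[2]) {
    out <- data.frame(window = names(windows), mean_hr_bpm = NA_real_)
    attr(out, "reason") <- "rr series does not span the analysis windows"
    return(out)
  }
  grid <- seq(span[1], span[2], by = 1000 / grid_hz)
  hr_i <- stats::approx(t, hr, xout = grid, rule = 1)$y
  base <- mean(hr_i[grid >= baseline[1] & grid < baseline[2]], na.rm = TRUE)
  means <- vapply(windows, function(w) {
    mean(hr_i[grid >= w[1] & grid < w[2]], na.rm = TRUE) - base
  }, numeric(1))
  data.frame(window = names(windows), mean_hr_bpm = unname(means),
             stringsAsFactors = FALSE)
}
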