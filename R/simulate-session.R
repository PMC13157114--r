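#' Counterbalanced condition table for the attention task
#'
#' Each emotion combination (angry-neutral, angry-happy, happy-neutral)
#' contributes `n_trials_atb` trials, split exactly equally over the side of
#' the higher-arousal face (left/right) and the two frequency assignments
#' (which flicker frequency tags which side). Trial order is randomized
#' under the current RNG state.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per trial: `trial_id`, `combination`,
#'   `side_high`, `freq_left`, `freq_right`, `emotion_left`, `emotion_right`,
#'   `onset_sample`.
#' @export
atb_condition_table <- function(config) {
  combos <- c("angry-neutral", "angry-happy", "happy-neutral")
  per_cell <- config$n_trials_atb / 4
  grid <- expand.grid(
    combination = combos,
    side_high = c("left", "right"),
    freq_assign = 1:2,
    rep = seq_len(per_cell),
    stringsAsFactors = FALSE
  )
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  n <- nrow(grid)

  f <- config$tag_freqs
  grid$freq_left <- ifelse(grid$freq_assign == 1, f[1], f[2])
  grid$freq_right <- ifelse(grid$freq_assign == 1, f[2], f[1])
  parts <- strsplit(grid$combination, "-", fixed = TRUE)
  emo_high <- vapply(parts, `[`, "", 1)
  emo_low <- vapply(parts, `[`, "", 2)
  grid$emotion_left <- ifelse(grid$side_high == "left", emo_high, emo_low)
  grid$emotion_right <- ifelse(grid$side_high == "right", emo_high, emo_low)

  iti <- stats::runif(n, config$iti_range_ms[1], config$iti_range_ms[2])
  onset_ms <- 2000 + cumsum(c(0, (3000 + iti)[-n]))
  grid$onset_sample <- round(onset_ms / 1000 * config$sample_rate) + 1L
  grid$trial_id <- seq_len(n)
  grid$rep <- NULL
  grid$freq_assign <- NULL
  rownames(grid) <- NULL
  grid[, c("trial_id", "combination", "side_high", "freq_left", "freq_right",
           "emotion_left", "emotion_right", "onset_sample")]
}

#' Condition table for the passive viewing task
#'
#' @param config a [sim_config()].
#' @return data.frame with `trial_id`, `expression`, `onset_sample`.
#' @export
viewing_condition_table <- function(config) {
  expr <- rep(c("angry", "happy", "neutral"), each = config$n_trials_viewing)
  expr <- expr[sample.int(length(expr))]
  n <- length(expr)
  iti <- stats::runif(n, config$viewing_iti_range_ms[1],
                      config$viewing_iti_range_ms[2])
  onset_ms <- 2000 + cumsum(c(0, (3000 + iti)[-n]))
  data.frame(
    trial_id = seq_len(n),
    expression = expr,
    onset_sample = round(onset_ms / 1000 * config$sample_rate) + 1L,
    stringsAsFactors = FALSE
  )
}

# Per-participant latent effects, drawn in a fixed order under the current
# RNG state so sessions are reproducible from the session seed.
#' @keywords internal
participant_effects <- function(config, group) {
  combos <- c("angry-neutral", "angry-happy", "happy-neutral")
  bias <- if (group == "stress") config$hemifield_bias else 0
  # left-stimulus gain, heterogeneous per combination x side-of-higher-arousal
  cell_gain <- matrix(
    exp(log(1 + bias) +
          stats::rnorm(6, 0, config$cell_gain_sd)),
    nrow = 3, dimnames = list(combos, c("left", "right"))
  )
  erp_scale <- max(0.1, 1 + stats::rnorm(1, 0, config$erp_subject_sd))
  g0 <- config$alpha_params$erd_gain[[group]]
  erd_gain <- min(1, g0 * exp(stats::rnorm(1, 0, config$alpha_params$erd_gain_sd)))
  scr_scale <- exp(stats::rnorm(1, 0, 0.3))
  rr_offset <- stats::rnorm(1, 0, 40)
  list(cell_gain = cell_gain, erp_scale = erp_scale, erd_gain = erd_gain,
       scr_scale = scr_scale, rr_offset = rr_offset, group = group)
}

# Per-trial tagged amplitudes implied by the generative model: each stimulus
# carries the base amplitude times its expression's attention weight; the
# left-hemifield stimulus is additionally scaled by the participant's cell
# gain (centered on 1 + hemifield_bias in the stress group); multiplicative
# log-normal trial noise on top.
#' @keywords internal
atb_trial_amplitudes <- function(conditions, config, pe) {
  w <- config$attention_weights
  base <- config$ssvep_amplitude_uv
  lg <- pe$cell_gain[cbind(conditions$combination, conditions$side_high)]
  n <- nrow(conditions)
  noise_l <- exp(stats::rnorm(n, 0, config$trial_amp_sd))
  noise_r <- exp(stats::rnorm(n, 0, config$trial_amp_sd))
  data.frame(
    trial_id = conditions$trial_id,
    amp_left = base * w[conditions$emotion_left] * lg * noise_l,
    amp_right = base * w[conditions$emotion_right] * noise_r
  )
}

# Scalp projection weight of a lateralized stimulus onto a channel:
# contralateral posterior channels get 1, ipsilateral get `ipsi_weight`,
# posterior midline the average; non-posterior channels 0.
#' @keywords internal
projection_weights <- function(channels, stim_side, ipsi_weight) {
  posterior <- c("O1", "O2", "Oz", "PO7", "PO8", "POz", "P7", "P8",
                 "P9", "P10", "P3", "P4", "Pz")
  hemi <- channel_hemisphere(channels)
  w <- numeric(length(channels))
  post <- channels %in% posterior
  w[post & hemi == "midline"] <- (1 + ipsi_weight) / 2
  w[post & hemi != "midline" & hemi != stim_side] <- 1
  w[post & hemi == stim_side] <- ipsi_weight
  w
}

#' Synthesize a continuous EEG recording for the attention task
#'
#' Two flickering stimuli per trial, lateralized to the hemifields with
#' contralateral scalp projection, on top of 1/f background noise.
#'
#' @param config a [sim_config()].
#' @param conditions condition table from [atb_condition_table()].
#' @param pe participant effects (internal); defaults drawn fresh.
#' @return a [continuous_recording()] with per-trial amplitudes attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_atb_recording <- function(config, conditions,
                                   pe = participant_effects(config, "control")) {
  fs <- config$sample_rate
  channels <- standard_montage()$label
  n_samples <- max(conditions$onset_sample) + round(3.2 * fs) + fs
  amps <- atb_trial_amplitudes(conditions, config, pe)
  data <- matrix(0, length(channels), n_samples,
                 dimnames = list(channels, NULL))
  for (ch in seq_along(channels)) {
    data[ch, ] <- pink_noise(n_samples, fs, config$noise$sd_uv,
                             config$noise$exponent)
  }
  trial_len <- round(3 * fs)
  t_rel <- seq_len(trial_len) / fs
  w_left <- projection_weights(channels, "left", config$ipsi_weight)
  w_right <- projection_weights(channels, "right", config$ipsi_weight)
  phases <- matrix(stats::runif(2 * nrow(conditions), 0, 2 * pi), ncol = 2)
  for (i in seq_len(nrow(conditions))) {
    idx <- conditions$onset_sample[i] + seq_len(trial_len) - 1L
    wave_l <- ssvep_waveform(t_rel, conditions$freq_left[i],
                             amps$amp_left[i], phases[i, 1])
    wave_r <- ssvep_waveform(t_rel, conditions$freq_right[i],
                             amps$amp_right[i], phases[i, 2])
    data[, idx] <- data[, idx] + outer(w_left, wave_l) + outer(w_right, wave_r)
  }
  rec <- continuous_recording(data, fs,
                              events = conditions[, c("onset_sample", "trial_id")])
  attr(rec, "ground_truth") <- list(amplitudes = amps, effects = pe)
  rec
}

#' Synthesize a continuous EEG recording for the passive viewing task
#'
#' Expression-dependent ERP templates over posterior/midline clusters, a
#' frontal alpha oscillation whose envelope drops to the participant's
#' desynchronization gain shortly after each stimulus onset, and 1/f noise.
#'
#' @inheritParams simulate_atb_recording
#' @param conditions condition table from [viewing_condition_table()].
#' @return a [continuous_recording()] with ground truth attached.
#' @export
simulate_viewing_recording <- function(config, conditions,
                                       pe = participant_effects(config, "control")) {
  fs <- config$sample_rate
  channels <- standard_montage()$label
  n_samples <- max(conditions$onset_sample) + round(3.2 * fs) + fs
  data <- matrix(0, length(channels), n_samples,
                 dimnames = list(channels, NULL))
  for (ch in seq_along(channels)) {
    data[ch, ] <- pink_noise(n_samples, fs, config$noise$sd_uv,
                             config$noise$exponent)
  }
  # frontal alpha with event-locked desynchronization of the envelope
  ap <- config$alpha_params
  t_all <- seq_len(n_samples) / fs
  alpha_phase <- stats::runif(1, 0, 2 * pi)
  carrier <- sin(2 * pi * ap$center_hz * t_all + alpha_phase)
  envelope <- rep(1, n_samples)
  onset_shift <- round(ap$desync_onset_ms / 1000 * fs)
  trial_len <- round(3 * fs)
  for (i in seq_len(nrow(conditions))) {
    from <- conditions$onset_sample[i] + onset_shift
    to <- min(conditions$onset_sample[i] + trial_len, n_samples)
    envelope[from:to] <- pe$erd_gain
  }
  alpha_sig <- ap$amplitude_uv * envelope * carrier
  for (ch in intersect(ap$channels, channels)) {
    data[ch, ] <- data[ch, ] + alpha_sig
  }
  # event-locked ERP templates
  t_ms <- (seq_len(trial_len) - 1) / fs * 1000
  gain <- config$erp_group_gain[[pe$group]] * pe$erp_scale
  templates <- lapply(c(angry = "angry", happy = "happy", neutral = "neutral"),
                      function(e) erp_template(t_ms, channels, e,
                                               config$erp_params, gain))
  for (i in seq_len(nrow(conditions))) {
    idx <- conditions$onset_sample[i] + seq_len(trial_len) - 1L
    data[, idx] <- data[, idx] + templates[[conditions$expression[i]]]
  }
  rec <- continuous_recording(data, fs,
                              events = conditions[, c("onset_sample", "trial_id")])
  attr(rec, "ground_truth") <- list(effects = pe, erd_gain = pe$erd_gain,
                                    erp_gain = gain)
  rec
}

#' Synthesize a skin conductance trace for a list of trial onsets
#'
#' Tonic level plus one bi-exponential response per responding trial and
#' Gaussian measurement noise.
#'
#' @param config a [sim_config()].
#' @param onsets_s trial onsets, seconds.
#' @param amplitudes_us per-trial response amplitude, uS (0 = no response).
#' @return data.frame `time_s`, `value_us`, with the per-trial ground-truth
#'   amplitudes attached as attribute `"ground_truth"`.
#' @export
simulate_scr_trace <- function(config, onsets_s, amplitudes_us) {
  sp <- config$scr_params
  fs <- sp$sample_rate
  t <- seq(0, max(onsets_s) + 12, by = 1 / fs)
  x <- rep(2, length(t))
  for (i in seq_along(onsets_s)) {
    if (amplitudes_us[i] > 0) {
      x <- x + scr_curve(t, onsets_s[i] + sp$latency_s, amplitudes_us[i],
                         sp$tau_rise_s, sp$tau_decay_s)
    }
  }
  if (sp$noise_sd_us > 0) x <- x + stats::rnorm(length(t), 0, sp$noise_sd_us)
  out <- data.frame(time_s = t, value_us = x)
  attr(out, "ground_truth") <- amplitudes_us
  out
}

# Draw per-trial SCR amplitudes for a set of condition labels.
#' @keywords internal
scr_trial_amplitudes <- function(config, cond_labels, pe, task = c("atb", "viewing")) {
  task <- match.arg(task)
  sp <- config$scr_params
  means <- if (task == "atb") sp$amplitude_us else sp$amplitude_viewing_us
  n <- length(cond_labels)
  responds <- stats::runif(n) < sp$response_prob
  amp <- means[cond_labels] * pe$scr_scale *
    exp(stats::rnorm(n, 0, sp$amplitude_sd))
  ifelse(responds, amp, 0)
}

#' Synthesize an RR-interval series with event-locked modulation
#'
#' Beats are laid down sequentially; each RR interval equals the baseline
#' plus the participant offset, plus a deceleration (RR lengthening) when
#' the beat falls 0-1 s after a stimulus onset and an acceleration (RR
#' shortening) 1-3 s after onset, plus Gaussian beat-to-beat noise.
#'
#' @param config a [sim_config()].
#' @param onsets_s stimulus onsets, seconds.
#' @param pe participant effects (internal).
#' @param duration_s total duration; defaults past the last onset.
#' @return data.frame `beat_time_ms`, `rr_ms`.
#' @export
simulate_rr_series <- function(config, onsets_s, pe = NULL,
                               duration_s = max(onsets_s) + 12) {
  rp <- config$rr_params
  base <- rp$baseline_rr_ms + if (is.null(pe)) 0 else pe$rr_offset
  beats <- numeric(0)
  t <- 0.2
  while (t < duration_s) {
    dt <- t - onsets_s
    dt <- dt[dt >= 0]
    mod <- 0
    if (length(dt) > 0) {
      last <- min(dt)
      if (last < 1) mod <- rp$decel_ms
      else if (last < 3) mod <- rp$accel_ms
    }
    rr <- base + mod + stats::rnorm(1, 0, rp$noise_sd_ms)
    rr <- max(rr, 300)
    beats <- c(beats, t + rr / 1000)
    t <- t + rr / 1000
  }
  data.frame(
    beat_time_ms = beats[-1] * 1000,
    rr_ms = diff(beats) * 1000
  )
}

#' Synthesize a six-sample saliva series for one participant
#'
#' @param config a [sim_config()].
#' @param group "stress" or "control".
#' @return data.frame `analyte`, `label`, `time_min`, `value`.
#' @export
simulate_saliva <- function(config, group) {
  sp <- config$saliva_params
  out <- list()
  for (analyte in c("cortisol", "saa")) {
    pars <- sp[[analyte]]
    subj <- stats::rnorm(1, 0, pars$subject_sd)
    vals <- pmax(0, pars$mean[group, ] + subj +
                   stats::rnorm(6, 0, pars$noise_sd))
    out[[analyte]] <- data.frame(
      analyte = analyte, label = sp$labels, time_min = sp$times_min,
      value = vals, stringsAsFactors = FALSE
    )
  }
  rbind(out$cortisol, out$saa)
}

#' Synthesize per-trial affective ratings for one participant
#'
#' @param config a [sim_config()].
#' @param group "stress" or "control".
#' @param conditions viewing condition table.
#' @return data.frame `trial_id`, `expression`, `arousal`, `valence` on the
#'   0-1 slider scale.
#' @export
simulate_ratings <- function(config, group, conditions) {
  rp <- config$ratings_params
  out <- conditions[, c("trial_id", "expression")]
  for (scale in c("arousal", "valence")) {
    pars <- rp[[scale]][[group]]
    subj <- stats::rnorm(3, 0, 0.95 * pars$sd)
    names(subj) <- names(pars$sd)
    e <- out$expression
    val <- pars$mean[e] + subj[e] +
      stats::rnorm(nrow(out), 0, pars$sd[e])
    out[[scale]] <- pmin(1, pmax(0, val))
  }
  out
}

#' Generate one participant's full synthetic session
#'
#' Produces every input the analysis pipeline consumes: continuous EEG with
#' event markers for both tasks, condition tables, skin conductance traces,
#' RR-interval series, a saliva series, and affective ratings, with all
#' ground-truth parameters attached. The session seed is a deterministic
#' function of the config seed, the participant index, and the group, so
#' identical calls are bit-identical.
#'
#' @param config a [sim_config()].
#' @param group "stress" or "control".
#' @param participant participant index within group.
#' @return list of class `stress_session`.
#' @export
generate_session <- function(config, group = c("stress", "control"),
                             participant = 1L) {
  group <- match.arg(group)
  validate_sim_config(config)
  seed <- (config$seed * 1009L + participant * 2L +
             (group == "control")) %% 2147483629L
  set.seed(seed)
  pe <- participant_effects(config, group)
  atb_cond <- atb_condition_table(config)
  atb_rec <- simulate_atb_recording(config, atb_cond, pe)
  view_cond <- viewing_condition_table(config)
  view_rec <- simulate_viewing_recording(config, view_cond, pe)
  fs <- config$sample_rate
  atb_onsets_s <- (atb_cond$onset_sample - 1) / fs
  view_onsets_s <- (view_cond$onset_sample - 1) / fs
  scr_amp_atb <- scr_trial_amplitudes(config, atb_cond$combination, pe, "atb")
  scr_amp_view <- scr_trial_amplitudes(config, view_cond$expression, pe,
                                       "viewing")
  session <- list(
    group = group,
    participant = participant,
    atb = list(recording = atb_rec, conditions = atb_cond),
    viewing = list(recording = view_rec, conditions = view_cond),
    scr = list(
      atb = simulate_scr_trace(config, atb_onsets_s, scr_amp_atb),
      viewing = simulate_scr_trace(config, view_onsets_s, scr_amp_view)
    ),
    rr = list(
      atb = simulate_rr_series(config, atb_onsets_s, pe),
      viewing = simulate_rr_series(config, view_onsets_s, pe)
    ),
    saliva = simulate_saliva(config, group),
    ratings = simulate_ratings(config, group, view_cond),
    ground_truth = list(effects = pe, config = config, seed = seed)
  )
  class(session) <- "stress_session"
  session
}

#' Simulate a study-scale attentional-bias experiment at the amplitude level
#'
#' Runs the same generative amplitude model as the waveform synthesizer
#' (shared code path) for every participant in both groups, but skips the
#' time-series stage: per-trial tagged amplitudes are drawn directly,
#' averaged within condition cells, and converted to attentional bias
#' scores. This is the generator used for study-scale parameter-recovery
#' runs, where synthesizing 80 full EEG recordings would add nothing to the
#' quantity under test (the bias-score distribution).
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this experiment.
#' @return data.frame `participant`, `group`, `combination`, `hemifield`,
#'   `abs` (one row per participant x combination x hemifield).
#' @export
simulate_bias_experiment <- function(config, seed = config$seed) {
  set.seed(seed %% 2147483629L)
  rows <- list()
  for (group in c("stress", "control")) {
    for (p in seq_len(config$n_participants_per_group)) {
      pe <- participant_effects(config, group)
      cond <- atb_condition_table(config)
      amps <- atb_trial_amplitudes(cond, config, pe)
      hi <- ifelse(cond$side_high == "left", amps$amp_left, amps$amp_right)
      lo <- ifelse(cond$side_high == "left", amps$amp_right, amps$amp_left)
      cells <- stats::aggregate(cbind(hi = hi, lo = lo),
                                by = list(combination = cond$combination,
                                          hemifield = cond$side_high),
                                FUN = mean)
      cells$abs <- abs_score(cells$hi, cells$lo)
      cells$participant <- paste0(substr(group, 1, 1), p)
      cells$group <- group
      rows[[length(rows) + 1]] <-
        cells[, c("participant", "group", "combination", "hemifield", "abs")]
    }
  }
  do.call(rbind, rows)
}

#' Simulate a study-scale ERP experiment at the component level
#'
#' Shares the amplitude model of the waveform generator (component base
#' amplitude, expression offset, hemisphere weight, group gain, participant
#' scale) and adds cell-level measurement noise scaled as trial-mean noise,
#' skipping waveform synthesis.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this experiment.
#' @return data.frame `participant`, `group`, `expression`, `component`,
#'   `hemisphere`, `amplitude`.
#' @export
simulate_erp_experiment <- function(config, seed = config$seed) {
  set.seed(seed %% 2147483629L)
  sd_cell <- config$noise$sd_uv / sqrt(config$n_trials_viewing)
  rows <- list()
  for (group in c("stress", "control")) {
    gain_g <- config$erp_group_gain[[group]]
    for (p in seq_len(config$n_participants_per_group)) {
      scale_i <- max(0.1, 1 + stats::rnorm(1, 0, config$erp_subject_sd))
      for (comp_name in names(config$erp_params)) {
        comp <- config$erp_params[[comp_name]]
        hemis <- if (comp_name == "LPP") "midline" else c("left", "right")
        for (e in c("angry", "happy", "neutral")) {
          for (h in hemis) {
            w <- if (h == "midline") mean(comp$hemi_weights)
                 else comp$hemi_weights[[h]]
            amp <- (comp$base_uv + comp$offsets_uv[[e]]) * gain_g * scale_i * w +
              stats::rnorm(1, 0, sd_cell)
            rows[[length(rows) + 1]] <- data.frame(
              participant = paste0(substr(group, 1, 1), p), group = group,
              expression = e, component = comp_name, hemisphere = h,
              amplitude = amp, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
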