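# Noise-free miniature configuration: every stochastic component silenced so
# scorers can be checked against injected ground truth.
quiet_config <- function(..., n_participants_per_group = 1, n_trials_atb = 4,
                         n_trials_viewing = 2, seed = 1L) {
  sim_config(
    n_participants_per_group = n_participants_per_group,
    n_trials_atb = n_trials_atb, n_trials_viewing = n_trials_viewing,
    cell_gain_sd = 0, trial_amp_sd = 0, erp_subject_sd = 0,
    noise = list(exponent = 1, sd_uv = 0),
    alpha_params = list(center_hz = 10, amplitude_uv = 4,
                        erd_gain = c(stress = 0.75, control = 0.55),
                        desync_onset_ms = 150, erd_gain_sd = 0,
                        channels = c("Fp1", "Fpz", "Fp2")),
    scr_params = list(tau_rise_s = 0.75, tau_decay_s = 6, latency_s = 1.8,
                      amplitude_us = c("angry-neutral" = 0.28,
                                       "angry-happy" = 0.32,
                                       "happy-neutral" = 0.38),
                      amplitude_viewing_us = c(angry = 0.30, happy = 0.28,
                                               neutral = 0.24),
                      amplitude_sd = 0, response_prob = 1,
                      sample_rate = 32, noise_sd_us = 0),
    rr_params = list(baseline_rr_ms = 800, decel_ms = 60, accel_ms = -40,
                     noise_sd_ms = 0),
    seed = seed, ...
  )
}

# Epoch set built directly from per-trial channel waveform functions:
# fun(t_ms) must return a channels x time matrix.
make_epochs <- function(fun, n_trials = 1, channels = c("Oz", "O1", "O2"),
                        sfreq = 512, tmin_ms = -200, tmax_ms = 3000,
                        conditions = NULL) {
  rel <- round(tmin_ms * sfreq / 1000):round(tmax_ms * sfreq / 1000)
  times_ms <- rel / sfreq * 1000
  dat <- array(0, c(n_trials, length(channels), length(times_ms)))
  for (tr in seq_len(n_trials)) dat[tr, , ] <- fun(times_ms)
  if (is.null(conditions)) conditions <- data.frame(trial_id = seq_len(n_trials))
  structure(
    list(data = dat, times_ms = times_ms, channels = channels,
         conditions = conditions, rejected = rep(FALSE, n_trials),
         reject_reason = rep("none", n_trials), reference = "none",
         sfreq = sfreq),
    class = "epoch_set"
  )
}

# Single-channel sinusoid epoch set (one trial).
tone_epochs <- function(freq, amplitude = 1, phase = 0.7, sfreq = 512,
                        channels = "Oz", tmin_ms = -200, tmax_ms = 3000) {
  make_epochs(function(t_ms) {
    matrix(rep(amplitude * sin(2 * pi * freq * t_ms / 1000 + phase),
               each = length(channels)),
           nrow = length(channels))
  }, n_trials = 1, channels = channels, sfreq = sfreq,
  tmin_ms = tmin_ms, tmax_ms = tmax_ms)
}

# Independent split-plot ANOVA oracle via base aov() error strata.
aov_oracle <- function(data, dv, id, between, within) {
  d <- data
  for (v in c(id, between, within)) d[[v]] <- factor(d[[v]])
  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", id, "/(", paste(within, collapse = " * "), "))")
  fit <- stats::aov(stats::as.formula(paste(dv, "~", rhs, "+", err)), data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm == "Residuals") next
      out[[nm]] <- list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
                        F = tab[i, "F value"])
    }
  }
  out
}
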