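#' Simulation configuration
#'
#' Builds the full parameter set for the synthetic-data generator. Defaults
#' encode the experiment the pipeline targets: 40 participants per group,
#' EEG sampled at 512 Hz, competing face pairs flickering at 12 and 15 Hz
#' lateralized to the two hemifields (96 trials per emotion combination,
#' counterbalanced over hemifield and frequency assignment), a passive
#' viewing task with 32 trials per expression, 3000 ms trials with
#' 4500-5500 ms inter-trial intervals, trough-to-peak skin conductance
#' responses, event-locked heart-rate deceleration/acceleration, and a
#' six-sample saliva series.
#'
#' Group effects are injected as parameter offsets with magnitudes that are
#' free generator parameters (not empirical claims): a left-visual-field
#' ssVEP gain (`hemifield_bias`) present only in the stress group, a global
#' multiplicative ERP attenuation in the stress group (`erp_group_gain`),
#' and an alpha desynchronization gain closer to 1 (weaker ERD) in the
#' stress group.
#'
#' @param n_participants_per_group participants per group.
#' @param n_trials_atb trials per emotion combination in the attention task;
#'   must be divisible by 4 so hemifield x frequency assignment is exactly
#'   counterbalanced.
#' @param n_trials_viewing trials per expression in the passive viewing task.
#' @param sample_rate EEG sampling rate, Hz.
#' @param tag_freqs the two flicker frequencies, Hz.
#' @param ssvep_amplitude_uv baseline tagged amplitude of one stimulus, uV.
#' @param attention_weights named nonnegative gains (angry, happy, neutral)
#'   applied to the tagged amplitude of a stimulus of that expression.
#' @param hemifield_bias nonnegative gain: the left-hemifield stimulus
#'   amplitude is multiplied by `1 + hemifield_bias` in the stress group.
#' @param cell_gain_sd SD (log scale) of the participant-by-cell
#'   heterogeneity of the left-stimulus gain; the dominant source of
#'   between-participant spread of bias scores.
#' @param trial_amp_sd SD (log scale) of per-trial amplitude fluctuations.
#' @param ipsi_weight ipsilateral scalp projection weight in `[0, 1)`;
#'   contralateral posterior channels receive weight 1.
#' @param erp_params list of per-component templates; see
#'   [default_erp_params()].
#' @param erp_group_gain named multiplicative gains (`stress`, `control`)
#'   applied to every ERP component amplitude.
#' @param erp_subject_sd SD of the participant multiplicative ERP scale
#'   (mean 1).
#' @param alpha_params list: `center_hz`, `amplitude_uv`, `erd_gain` (named
#'   per-group envelope gain in `(0, 1]` applied after `desync_onset_ms`),
#'   `desync_onset_ms`, `erd_gain_sd` (participant spread, log scale), and
#'   `channels`.
#' @param noise list: `exponent` of the 1/f background spectrum and `sd_uv`.
#' @param scr_params list: `tau_rise_s`, `tau_decay_s`, `latency_s`,
#'   `amplitude_us` (named per ATB combination), `amplitude_viewing_us`
#'   (named per expression), `amplitude_sd` (log scale), `response_prob`,
#'   `sample_rate`, `noise_sd_us`.
#' @param rr_params list: `baseline_rr_ms`, `decel_ms` (RR lengthening in
#'   the first second after onset), `accel_ms` (RR shortening at 1-3 s),
#'   `noise_sd_ms`.
#' @param saliva_params list with per-analyte, per-group 6-point mean
#'   trajectories, noise SDs, subject intercept SDs, and `times_min`.
#'   Sample labels are (t-30, t-pre, t+00, t+15, t+30, t+50); "t-pre" maps
#'   to -5 min by default.
#' @param ratings_params list of per-group, per-expression means and SDs of
#'   arousal and valence ratings on the 0-1 slider scale.
#' @param iti_range_ms inter-trial interval range for the attention task,
#'   ms; the minimum must leave room for the -200..3000 ms epoch.
#' @param viewing_iti_range_ms inter-trial interval range for the passive
#'   viewing task, ms. The default leaves a minority of trials with less
#'   than 7500 ms between onsets, which the skin conductance scorer excludes
#'   as short trials.
#' @param seed integer master seed; identical seed and config give
#'   bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_participants_per_group = 40,
                       n_trials_atb = 96,
                       n_trials_viewing = 32,
                       sample_rate = 512,
                       tag_freqs = c(12, 15),
                       ssvep_amplitude_uv = 1.5,
                       attention_weights = c(angry = 1, happy = 1, neutral = 1),
                       hemifield_bias = 0.35,
                       cell_gain_sd = 1.0,
                       trial_amp_sd = 0.3,
                       ipsi_weight = 0.4,
                       erp_params = default_erp_params(),
                       erp_group_gain = c(stress = 0.85, control = 1),
                       erp_subject_sd = 0.2,
                       alpha_params = list(
                         center_hz = 10, amplitude_uv = 4,
                         erd_gain = c(stress = 0.75, control = 0.55),
                         desync_onset_ms = 150, erd_gain_sd = 0.1,
                         channels = c("Fp1", "Fpz", "Fp2")
                       ),
                       noise = list(exponent = 1, sd_uv = 2),
                       scr_params = list(
                         tau_rise_s = 0.75, tau_decay_s = 6, latency_s = 1.8,
                         amplitude_us = c("angry-neutral" = 0.28,
                                          "angry-happy" = 0.32,
                                          "happy-neutral" = 0.38),
                         amplitude_viewing_us = c(angry = 0.30, happy = 0.28,
                                                  neutral = 0.24),
                         amplitude_sd = 0.4, response_prob = 0.75,
                         sample_rate = 32, noise_sd_us = 0.003
                       ),
                       rr_params = list(baseline_rr_ms = 800, decel_ms = 60,
                                        accel_ms = -40, noise_sd_ms = 15),
                       saliva_params = default_saliva_params(),
                       ratings_params = default_ratings_params(),
                       iti_range_ms = c(4500, 5500),
                       viewing_iti_range_ms = c(4400, 5400),
                       seed = 1L) {
  cfg <- list(
    n_participants_per_group = n_participants_per_group,
    n_trials_atb = n_trials_atb,
    n_trials_viewing = n_trials_viewing,
    sample_rate = sample_rate,
    tag_freqs = tag_freqs,
    ssvep_amplitude_uv = ssvep_amplitude_uv,
    attention_weights = attention_weights,
    hemifield_bias = hemifield_bias,
    cell_gain_sd = cell_gain_sd,
    trial_amp_sd = trial_amp_sd,
    ipsi_weight = ipsi_weight,
    erp_params = erp_params,
    erp_group_gain = erp_group_gain,
    erp_subject_sd = erp_subject_sd,
    alpha_params = alpha_params,
    noise = noise,
    scr_params = scr_params,
    rr_params = rr_params,
    saliva_params = saliva_params,
    ratings_params = ratings_params,
    iti_range_ms = iti_range_ms,
    viewing_iti_range_ms = viewing_iti_range_ms,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants_per_group >= 1,
            cfg$n_trials_atb >= 4, cfg$n_trials_viewing >= 1,
            cfg$sample_rate > 0)
  if (cfg$n_trials_atb %% 4 != 0) {
    stop("n_trials_atb must be divisible by 4 for exact counterbalancing")
  }
  if (length(cfg$tag_freqs) != 2 || cfg$tag_freqs[1] == cfg$tag_freqs[2]) {
    stop("tag_freqs must be two distinct frequencies")
  }
  if (any(cfg$tag_freqs >= cfg$sample_rate / 2)) {
    stop("tag frequencies must be below the Nyquist frequency")
  }
  if (any(cfg$attention_weights < 0) || cfg$hemifield_bias < 0 ||
      cfg$ssvep_amplitude_uv < 0 || cfg$noise$sd_uv < 0) {
    stop("gains, amplitudes and noise SDs must be nonnegative")
  }
  if (cfg$ipsi_weight < 0 || cfg$ipsi_weight >= 1) {
    stop("ipsi_weight must be in [0, 1)")
  }
  g <- cfg$alpha_params$erd_gain
  if (any(g <= 0) || any(g > 1)) stop("erd_gain must be in (0, 1]")
  if (cfg$scr_params$tau_decay_s <= cfg$scr_params$tau_rise_s ||
      cfg$scr_params$tau_rise_s <= 0) {
    stop("scr_params must satisfy tau_decay_s > tau_rise_s > 0")
  }
  epoch_span_ms <- 3000 + 200
  if (min(cfg$iti_range_ms) < epoch_span_ms ||
      min(cfg$viewing_iti_range_ms) < epoch_span_ms) {
    stop("inter-trial intervals shorter than the epoch span are not allowed")
  }
  invisible(cfg)
}

#' Default ERP component templates
#'
#' Each component is a cosine-tapered plateau ("bump") whose plateau height
#' equals the amplitude parameter, so the mean voltage over the component's
#' canonical scoring window and the windowed peak both recover the injected
#' amplitude. Hemisphere weights average to 1 within each cluster; the N170
#' and EPN are projected right > left to emulate right-lateralized face
#' processing.
#'
#' @return named list of component templates with fields `center_ms`,
#'   `flat_halfwidth_ms`, `ramp_ms`, `base_uv`, `offsets_uv` (per
#'   expression), `cluster`, `hemi_weights` (left, right).
#' @export
default_erp_params <- function() {
  list(
    P1 = list(center_ms = 100, flat_halfwidth_ms = 15, ramp_ms = 20,
              base_uv = 5,
              offsets_uv = c(angry = 0, happy = 0, neutral = 0),
              cluster = c("O1", "O2", "PO7", "PO8", "P9", "P10"),
              hemi_weights = c(left = 0.9, right = 1.1)),
    N170 = list(center_ms = 165, flat_halfwidth_ms = 25, ramp_ms = 20,
                base_uv = -3,
                offsets_uv = c(angry = -0.8, happy = 0, neutral = 0),
                cluster = c("PO7", "PO8", "P9", "P10"),
                hemi_weights = c(left = 0.8, right = 1.2)),
    EPN = list(center_ms = 270, flat_halfwidth_ms = 25, ramp_ms = 25,
               base_uv = -2,
               offsets_uv = c(angry = -0.5, happy = 0, neutral = 0),
               cluster = c("P7", "P8", "PO7", "PO8", "P9", "P10"),
               hemi_weights = c(left = 0.85, right = 1.15)),
    LPP = list(center_ms = 700, flat_halfwidth_ms = 250, ramp_ms = 100,
               base_uv = 3,
               offsets_uv = c(angry = 0.5, happy = 0.2, neutral = 0),
               cluster = c("Cz", "CPz", "Pz", "POz"),
               hemi_weights = c(left = 1, right = 1))
  )
}

#' Default saliva trajectories
#'
#' Six-sample mean trajectories per group for cortisol (nmol/L) and salivary
#' alpha-amylase (U/mL): cortisol declines across the session in both groups
#' and alpha-amylase peaks immediately after the stressor in both groups.
#' Sampling times come from the sample labels, with the pre-stressor
#' baseline ("t-pre") mapped to -5 min.
#'
#' @return list with `times_min`, `labels`, and per-analyte group means and
#'   noise parameters.
#' @export
default_saliva_params <- function() {
  list(
    times_min = c(-30, -5, 0, 15, 30, 50),
    labels = c("t-30", "t-pre", "t+00", "t+15", "t+30", "t+50"),
    cortisol = list(
      mean = rbind(stress = c(15, 13.5, 12.5, 11.5, 10.5, 9.5),
                   control = c(15, 13.4, 12.3, 11.3, 10.3, 9.3)),
      subject_sd = 3, noise_sd = 1.2
    ),
    saa = list(
      mean = rbind(stress = c(80, 85, 120, 95, 88, 85),
                   control = c(78, 83, 116, 93, 86, 83)),
      subject_sd = 25, noise_sd = 12
    )
  )
}

#' Default affective-rating parameters
#'
#' Per-group, per-expression means and between-participant SDs of arousal
#' and valence on the 0-1 slider scale: angry and happy faces more arousing
#' than neutral, angry unpleasant and happy pleasant, with the stress group
#' rating angry faces slightly more unpleasant.
#'
#' @return nested list `[[scale]][[group]]` with `mean` and `sd` named by
#'   expression.
#' @export
default_ratings_params <- function() {
  list(
    arousal = list(
      stress = list(mean = c(angry = 0.58, happy = 0.52, neutral = 0.37),
                    sd = c(angry = 0.14, happy = 0.17, neutral = 0.14)),
      control = list(mean = c(angry = 0.55, happy = 0.51, neutral = 0.42),
                     sd = c(angry = 0.14, happy = 0.13, neutral = 0.11))
    ),
    valence = list(
      stress = list(mean = c(angry = 0.21, happy = 0.79, neutral = 0.43),
                    sd = c(angry = 0.086, happy = 0.080, neutral = 0.057)),
      control = list(mean = c(angry = 0.26, happy = 0.75, neutral = 0.43),
                     sd = c(angry = 0.095, happy = 0.10, neutral = 0.050))
    )
  )
}
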