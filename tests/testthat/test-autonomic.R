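scr_fixture <- function(amplitude, onset_s = 2, latency_s = 1.8, fs = 32,
                        dur_s = 15) {
  t <- seq(0, dur_s, by = 1 / fs)
  data.frame(time_s = t,
             value_us = 2 + scr_curve(t, onset_s + latency_s, amplitude))
}

test_that("trough-to-peak scoring recovers bi-exponential amplitudes", {
  sc <- score_scr(scr_fixture(0.5), onset_s = 2)
  expect_true(sc$valid)
  expect_equal(sc$amplitude_us, 0.5, tolerance = 0.02)
  expect_gt(sc$peak_ms, sc$valley_ms)
  expect_equal(sc$exclusion_reason, "none")
})

test_that("the 0.02 uS validity boundary is exact", {
  low <- score_scr(scr_fixture(0.019), onset_s = 2)
  expect_false(low$valid)
  expect_equal(low$exclusion_reason, "below_threshold")
  hi <- score_scr(scr_fixture(0.021), onset_s = 2)
  expect_true(hi$valid)
  # amplitude exactly at threshold is valid ("below 0.02" is excluded)
  flat <- data.frame(time_s = seq(0, 15, by = 1 / 32), value_us = 2)
  flat$value_us[flat$time_s >= 5.5 & flat$time_s <= 6] <- 2.02
  at <- score_scr(flat, onset_s = 2)
  expect_equal(at$amplitude_us, 0.02)
  expect_true(at$valid)
})

test_that("flat and short traces are excluded with the right reason", {
  flat <- data.frame(time_s = seq(0, 15, by = 1 / 32), value_us = 2)
  sc <- score_scr(flat, onset_s = 2)
  expect_false(sc$valid)
  expect_equal(sc$amplitude_us, 0)
  expect_equal(sc$exclusion_reason, "below_threshold")
  short <- data.frame(time_s = seq(0, 8, by = 1 / 32), value_us = 2)
  sc2 <- score_scr(short, onset_s = 2) # only 6 s post onset
  expect_equal(sc2$exclusion_reason, "short_trial")
  # decreasing trace after the valley: no peak after valley
  t <- seq(0, 15, by = 1 / 32)
  falling <- data.frame(time_s = t, value_us = 10 - t)
  sc3 <- score_scr(falling, onset_s = 2, peak_window = c(1500, 2000))
  expect_equal(sc3$exclusion_reason, "no_peak_after_valley")
})

test_that("scoring matches valley/peak window definitions", {
  t <- seq(0, 15, by = 1 / 32)
  x <- rep(2, length(t))
  x[t >= 2 + 2 & t < 2 + 2.5] <- 1.5 # valley at +2000 ms
  x[t >= 2 + 5 & t < 2 + 5.5] <- 2.6 # peak at +5000 ms
  sc <- score_scr(data.frame(t, x), onset_s = 2)
  expect_equal(sc$valley_us, 1.5)
  expect_equal(sc$peak_us, 2.6)
  expect_equal(sc$amplitude_us, 1.1)
  expect_equal(sc$valley_ms, 2000, tolerance = 50)
  expect_equal(sc$peak_ms, 5000, tolerance = 50)
})

test_that("participant inclusion needs every cell at the minimum count", {
  mk_scores <- function(valid_per_cond) {
    do.call(rbind, lapply(seq_along(valid_per_cond), function(ci) {
      n <- 8
      v <- c(rep(TRUE, valid_per_cond[ci]), rep(FALSE, n - valid_per_cond[ci]))
      data.frame(trial_id = (ci - 1) * n + seq_len(n),
                 amplitude_us = ifelse(v, 0.3, 0.001), valid = v)
    }))
  }
  conds <- data.frame(trial_id = 1:24,
                      condition = rep(c("a", "b", "c"), each = 8))
  expect_true(participant_scr_cells(mk_scores(c(5, 5, 5)), conds)$included)
  expect_false(participant_scr_cells(mk_scores(c(5, 5, 4)), conds)$included)
  # raising min_valid never includes anyone new
  for (v in list(c(5, 6, 7), c(8, 8, 8), c(2, 8, 8))) {
    inc <- vapply(1:8, function(m) {
      participant_scr_cells(mk_scores(v), conds, min_valid = m)$included
    }, logical(1))
    expect_true(all(diff(inc) <= 0))
  }
})

test_that("exclusion counts match a brute-force recount on a seeded fixture", {
  cfg <- sim_config(n_participants_per_group = 1, n_trials_atb = 24,
                    n_trials_viewing = 2, seed = 77)
  s <- generate_session(cfg, "stress", 1)
  onsets <- (s$atb$conditions$onset_sample - 1) / cfg$sample_rate
  scores <- score_scr_trials(s$scr$atb, onsets, s$atb$conditions$trial_id)
  conds <- data.frame(trial_id = s$atb$conditions$trial_id,
                      condition = s$atb$conditions$combination)
  res <- participant_scr_cells(scores, conds)
  m <- merge(scores, conds, by = "trial_id")
  brute <- tapply(m$valid, m$condition, sum)
  expect_equal(res$cells$n_valid[match(names(brute), res$cells$condition)],
               unname(as.vector(brute)))
  expect_equal(res$included, all(brute >= 5))
})

test_that("scr amplitudes recover within 0.02 uS at low noise", {
  # well-separated responses so only measurement noise limits recovery
  cfg <- quiet_config(seed = 51)
  cfg$scr_params$noise_sd_us <- 0.005
  onsets <- seq(5, 245, by = 30)
  set.seed(52)
  truth <- runif(length(onsets), 0.1, 0.6)
  trace <- simulate_scr_trace(cfg, onsets, truth)
  scores <- score_scr_trials(preprocess_scr(trace), onsets)
  expect_true(all(scores$valid))
  expect_lt(max(abs(scores$amplitude_us - truth)), 0.02)
})

test_that("scr scoring from a session matches amplitudes up to overlap", {
  # consecutive trials about 8 s apart leave a decaying tail of the
  # previous response under the next valley window; recovery is unbiased
  # only to within that overlap
  cfg <- quiet_config(seed = 51)
  s <- generate_session(cfg, "control", 1)
  onsets <- (s$atb$conditions$onset_sample - 1) / cfg$sample_rate
  scores <- score_scr_trials(s$scr$atb, onsets)
  truth <- attr(s$scr$atb, "ground_truth")
  expect_lt(max(abs(scores$amplitude_us - truth)), 0.06)
  expect_gt(cor(scores$amplitude_us, truth), 0.95)
})

test_that("heart-rate window means are baseline-corrected correctly", {
  # constant RR: all window means zero after baseline correction
  beats <- seq(1000, 20000, by = 1000)
  rr <- data.frame(beat_time_ms = beats, rr_ms = 1000)
  h <- hr_windows(rr, onset_ms = 10000)
  expect_equal(h$mean_hr_bpm, rep(0, 4), tolerance = 1e-9)
  # RR step 1000 -> 1200 at onset: deceleration window mean is negative
  rr2 <- rr
  rr2$rr_ms[rr2$beat_time_ms > 10000] <- 1200
  h2 <- hr_windows(rr2, onset_ms = 10000)
  expect_lt(h2$mean_hr_bpm[h2$window == "0-1000"], 0)
  expect_lt(h2$mean_hr_bpm[h2$window == "0-7500"],
            h2$mean_hr_bpm[h2$window == "0-1000"])
  # constant RR of 600 ms: instantaneous HR is 100 bpm everywhere
  rr3 <- data.frame(beat_time_ms = seq(600, 20000, by = 600), rr_ms = 600)
  h3 <- hr_windows(rr3, onset_ms = 10000)
  expect_equal(h3$mean_hr_bpm, rep(0, 4), tolerance = 1e-9) # 100 - 100
  expect_equal(unique(60000 / rr3$rr_ms), 100)
  # series not spanning the windows: NA with a reason
  h4 <- hr_windows(rr[1:3, ], onset_ms = 10000)
  expect_true(all(is.na(h4$mean_hr_bpm)))
  expect_match(attr(h4, "reason"), "span")
})

test_that("simulated RR series shows deceleration then acceleration", {
  cfg <- quiet_config(seed = 61)
  onsets <- c(20, 40)
  rr <- simulate_rr_series(cfg, onsets)
  h <- hr_windows(rr, onset_ms = 20000)
  expect_lt(h$mean_hr_bpm[h$window == "0-1000"], 0)
  expect_gt(h$mean_hr_bpm[h$window == "1000-3000"],
            h$mean_hr_bpm[h$window == "0-1000"])
})
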