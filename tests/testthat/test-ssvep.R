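test_that("fft amplitude is exact for bin-frequency sinusoids", {
  ep <- tone_epochs(12, amplitude = 1)
  amp <- fft_amplitude(ep, freqs = 12, window_ms = c(0, 3000))
  expect_equal(amp["12Hz", "Oz"], 1, tolerance = 0.01)
  # non-integer cycle count warns (34.8 cycles of 12 Hz in 100-3000 ms)
  expect_warning(fft_amplitude(ep, freqs = 12, window_ms = c(100, 3000)),
                 "integer number of cycles")
  silent <- make_epochs(function(t) matrix(0, 1, length(t)), channels = "Oz")
  expect_equal(unname(fft_amplitude(silent, freqs = c(12, 15))),
               matrix(0, 2, 1))
  two <- make_epochs(function(t) {
    matrix(sin(2 * pi * 12 * t / 1000) + 2 * sin(2 * pi * 15 * t / 1000 + 1),
           1, length(t))
  }, channels = "Oz")
  amp2 <- fft_amplitude(two, freqs = c(12, 15), window_ms = c(0, 3000))
  expect_equal(unname(amp2[, 1]), c(1, 2), tolerance = 0.02)
})

test_that("morlet envelope has unit gain and tracks amplitude steps", {
  ep <- tone_epochs(12, amplitude = 1)
  tfr <- morlet_amplitude(ep, freqs = 12)
  mid <- tfr$times_ms >= 500 & tfr$times_ms <= 2500
  expect_equal(mean(tfr$amplitude[1, 1, 1, mid]), 1, tolerance = 0.05)
  zero <- make_epochs(function(t) matrix(0, 1, length(t)), channels = "Oz")
  expect_true(all(morlet_amplitude(zero, freqs = 12)$amplitude == 0))
  step <- make_epochs(function(t) {
    a <- ifelse(t < 1500, 1, 2)
    matrix(a * sin(2 * pi * 12 * t / 1000), 1, length(t))
  }, channels = "Oz")
  env <- morlet_amplitude(step, freqs = 12)$amplitude[1, 1, 1, ]
  tt <- step$times_ms
  expect_equal(mean(env[tt > 500 & tt < 1200]), 1, tolerance = 0.05)
  expect_equal(mean(env[tt > 1800 & tt < 2500]), 2, tolerance = 0.1)
  trans <- env[tt >= 1200 & tt <= 1800]
  expect_true(all(diff(trans) > -0.01)) # monotone transition between plateaus
  expect_error(morlet_amplitude(ep, freqs = 300), "Nyquist")
})

test_that("windowed morlet amplitude matches the leakage-free FFT oracle", {
  for (freq in c(12, 15)) {
    for (amp in c(0.7, 1.8)) {
      ep <- tone_epochs(freq, amplitude = amp)
      tfr <- morlet_amplitude(ep, freqs = freq)
      morlet_val <- tagged_amplitude(tfr, freq, window_ms = c(500, 2500))
      fft_val <- fft_amplitude(ep, freqs = freq, window_ms = c(0, 3000))[1, 1]
      expect_equal(morlet_val, fft_val, tolerance = 0.05 * amp,
                   ignore_attr = TRUE)
    }
  }
})

test_that("tagged amplitude averages the requested cluster only", {
  ep <- make_epochs(function(t) {
    rbind(2 * sin(2 * pi * 12 * t / 1000),
          2 * sin(2 * pi * 12 * t / 1000),
          4 * sin(2 * pi * 12 * t / 1000))
  }, channels = c("O1", "O2", "Oz"))
  tfr <- morlet_amplitude(ep, freqs = 12)
  both <- tagged_amplitude(tfr, 12, c(500, 2500))
  no_oz <- tagged_amplitude(tfr, 12, c(500, 2500), channels = c("O1", "O2"))
  expect_equal(no_oz, 2, tolerance = 0.05)
  expect_equal(both, (2 + 2 + 4) / 3, tolerance = 0.1)
})

test_that("bias score arithmetic, range, and antisymmetry hold", {
  expect_equal(abs_score(1.5, 0.5), 0.5)
  expect_equal(abs_score(2, 2), 0)
  expect_equal(abs_score(2, 0), 1)
  expect_warning(expect_true(is.na(abs_score(0, 0))), "undefined")
  expect_error(abs_score(-1, 1), "nonnegative")
  set.seed(5)
  a <- runif(500, 0, 10)
  b <- runif(500, 0, 10)
  s <- abs_score(a, b)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(abs_score(b, a), -s)
})

# Expected cluster-mean tagged amplitude of two concurrent lateralized
# tags through freq/2-cycle wavelets, derived independently of the
# implementation: the analyzing wavelet at one tag passes the other tag
# with Gaussian spectral gain exp(-df^2 / (2 sigma_f^2)), sigma_f =
# freq/cycles = 2 Hz for both tags; the envelope of the two leaked tones
# averages over their beat phase; and each cluster channel mixes the two
# stimuli with its projection weights (contralateral 1, ipsilateral 0.4,
# midline 0.7): three channels on each side plus the midline.
leaky_amplitude <- function(a_own, a_other, tags = c(12, 15),
                            ipsi = 0.4) {
  leak <- exp(-diff(tags)^2 / (2 * 2^2))
  phi <- exp(1i * seq(0, 2 * pi, length.out = 721)[-721])
  beat <- function(w_own, w_other) {
    mean(Mod(w_own * a_own + leak * w_other * a_other * phi))
  }
  mid <- (1 + ipsi) / 2
  (3 * beat(1, ipsi) + 3 * beat(ipsi, 1) + beat(mid, mid)) / 7
}

test_that("bias table recovers injected attention gain at zero noise", {
  cfg <- quiet_config(attention_weights = c(angry = 1.5, happy = 1,
                                            neutral = 1),
                      seed = 21)
  s <- generate_session(cfg, "control", 1)
  ep <- epoch(s$atb$recording, conditions = s$atb$conditions)
  ep <- baseline_correct(ep)
  tab <- abs_table(ep, "p1", "control")
  expect_equal(nrow(tab), 30) # 5 windows x 3 combinations x 2 hemifields
  glob <- tab[tab$window == "100-3000", ]
  # angry tagged 1.5x; with cross-tag wavelet leakage the expected score is
  # the leakage-corrected normalized difference (~0.15 rather than the
  # leakage-free 0.2)
  hi <- leaky_amplitude(1.5, 1)
  lo <- leaky_amplitude(1, 1.5)
  expected <- (hi - lo) / (hi + lo)
  angry_cells <- glob$combination %in% c("angry-neutral", "angry-happy")
  expect_lt(max(abs(glob$abs[angry_cells] - expected)), 0.025)
  expect_lt(max(abs(glob$abs[!angry_cells])), 0.03)
  # ratio of cluster-mean tagged amplitudes matches the leakage oracle
  tfr <- morlet_amplitude(ep, freqs = cfg$tag_freqs,
                          channels = ssvep_cluster())
  cond <- s$atb$conditions
  f_high <- ifelse(cond$side_high == "left", cond$freq_left, cond$freq_right)
  i <- which(cond$combination == "angry-neutral")[1]
  amp_hi <- tagged_amplitude(tfr, f_high[i], c(100, 3000))[i]
  amp_lo <- tagged_amplitude(tfr, setdiff(cfg$tag_freqs, f_high[i]),
                             c(100, 3000))[i]
  expect_equal(amp_hi / amp_lo, hi / lo, tolerance = 0.1)
})

test_that("rejected trials are excluded from cell averages", {
  cfg <- quiet_config(attention_weights = c(angry = 2, happy = 1, neutral = 1),
                      n_trials_atb = 8, seed = 22)
  s <- generate_session(cfg, "control", 1)
  ep <- baseline_correct(epoch(s$atb$recording, conditions = s$atb$conditions))
  keep_one <- ep
  an <- which(ep$conditions$combination == "angry-neutral" &
                ep$conditions$side_high == "left")
  keep_one$rejected[an[-1]] <- TRUE
  t_all <- abs_table(ep, windows = list("100-3000" = c(100, 3000)))
  t_one <- abs_table(keep_one, windows = list("100-3000" = c(100, 3000)))
  pick <- t_all$combination == "angry-neutral" & t_all$hemifield == "left"
  # noise-free up to per-trial beat phases between the two tags
  expect_equal(t_one$abs[pick], t_all$abs[pick], tolerance = 0.04)
})
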