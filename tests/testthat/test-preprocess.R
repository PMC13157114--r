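make_rec <- function(x, fs = 512, labels = "Oz", events = NULL) {
  continuous_recording(matrix(rep(x, each = length(labels)),
                              nrow = length(labels),
                              dimnames = list(labels, NULL)),
                       fs, events = events)
}

test_that("band-pass preserves the passband and removes offsets", {
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  rec <- make_rec(sin(2 * pi * 10 * t) + 100, fs)
  y <- bandpass(rec)$data[1, ]
  mid <- 5000:6000
  expect_equal((max(y[mid]) - min(y[mid])) / 2, 1, tolerance = 0.01)
  expect_lt(abs(mean(y[mid])), 0.05)
  # one octave beyond the 40 Hz edge: at least 20 dB down
  y80 <- bandpass(make_rec(sin(2 * pi * 80 * t), fs))$data[1, ]
  expect_lt(max(abs(y80[mid])), 10^(-20 / 20))
  expect_error(bandpass(rec, low = 40, high = 10), "low < high")
})

test_that("notch removes line noise, spares neighbours, and is idempotent", {
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  mid <- 5000:6000
  y50 <- notch(make_rec(sin(2 * pi * 50 * t), fs))$data[1, ]
  expect_lt(max(abs(y50[mid])), 0.1)
  y10 <- notch(make_rec(sin(2 * pi * 10 * t), fs))$data[1, ]
  expect_equal(max(y10[mid]), 1, tolerance = 0.02)
  once <- notch(make_rec(sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t), fs))
  twice <- notch(once)
  expect_equal(twice$data[1, mid], once$data[1, mid], tolerance = 1e-4)
})

test_that("epoching follows the rounding convention and flags edge events", {
  fs <- 512
  x <- rnorm(20000)
  rec <- make_rec(x, fs, events = data.frame(onset_sample = c(1L, 5000L, 9000L),
                                             trial_id = 1:3))
  ep <- epoch(rec)
  expect_equal(dim(ep$data)[3], 1639)
  expect_true(ep$rejected[1])
  expect_equal(ep$reject_reason[1], "edge")
  expect_false(any(ep$rejected[2:3]))
  expect_equal(ep$conditions$trial_id, 1:3)
  # epochs reproduce the raw samples in event order
  expect_equal(ep$data[2, 1, which(ep$times_ms == 0)], x[5000])
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- make_epochs(function(t) matrix(7, 3, length(t)), n_trials = 2)
  bc <- baseline_correct(ep)
  expect_true(all(abs(bc$data) < 1e-12))
  set.seed(1)
  ep2 <- make_epochs(function(t) matrix(rnorm(3 * length(t)), 3), n_trials = 4)
  bc2 <- baseline_correct(ep2)
  sel <- bc2$times_ms >= -200 & bc2$times_ms <= 0
  expect_lt(max(abs(apply(bc2$data[, , sel], c(1, 2), mean))), 1e-9)
})

test_that("amplitude rejection is exact at the threshold and monotone", {
  ep <- make_epochs(function(t) matrix(0, 2, length(t)), n_trials = 3,
                    channels = c("O1", "O2"))
  ep$data[2, 1, 100] <- 151
  ep$data[3, 2, 50] <- -120
  r <- reject_amplitude(ep, 150)
  expect_equal(r$rejected, c(FALSE, TRUE, FALSE))
  expect_equal(r$reject_reason[2], "amplitude")
  set.seed(2)
  epn <- make_epochs(function(t) matrix(rnorm(2 * length(t), sd = 80), 2),
                     n_trials = 20, channels = c("O1", "O2"))
  counts <- vapply(seq(50, 300, by = 25),
                   function(th) sum(reject_amplitude(epn, th)$rejected),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(reject_amplitude(ep, -1), "positive")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(3)
  ep <- make_epochs(function(t) matrix(rnorm(3 * length(t)), 3), n_trials = 2)
  ar <- average_reference(ep)
  expect_lt(max(abs(apply(ar$data, c(1, 3), mean))), 1e-9)
  ar2 <- average_reference(ar)
  expect_equal(ar2$data, ar$data, tolerance = 1e-12)
  same <- make_epochs(function(t) matrix(sin(t / 50), 3, length(t), byrow = TRUE),
                      n_trials = 1)
  expect_lt(max(abs(average_reference(same)$data)), 1e-12)
})

test_that("bad channels are rebuilt from neighbours", {
  fs <- 512
  t <- seq(0, 4, by = 1 / fs)
  labels <- standard_montage()$label
  sig <- sin(2 * pi * 7 * t)
  data <- matrix(rep(sig, each = length(labels)), nrow = length(labels),
                 dimnames = list(labels, NULL))
  rec <- continuous_recording(data, fs)
  rec$data["Oz", ] <- 40 # corrupted
  fixed <- interpolate_channels(rec, "Oz")
  expect_equal(fixed$data["Oz", ], sig, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(interpolate_channels(rec, character(0)), rec)
  expect_equal(fixed$data["O1", ], rec$data["O1", ])
})

test_that("interpolating one posterior channel keeps tagged amplitude near truth", {
  cfg <- quiet_config(seed = 11)
  s <- generate_session(cfg, "control", 1)
  rec <- s$atb$recording
  rec$data["Oz", ] <- 500 # kill the channel, then interpolate it back
  rec2 <- interpolate_channels(rec, "Oz")
  ep <- epoch(rec2, conditions = s$atb$conditions)
  ep <- baseline_correct(ep)
  tab <- abs_table(ep, windows = list("100-3000" = c(100, 3000)))
  # symmetric noise-free generator: scores stay near zero after repair
  expect_lt(max(abs(tab$abs)), 0.15)
})

test_that("the preprocessing chain records its step order", {
  cfg <- quiet_config(seed = 4)
  s <- generate_session(cfg, "control", 1)
  ep <- preprocess_recording(s$atb$recording, s$atb$conditions)
  expect_equal(attr(ep, "steps"),
               c("bandpass", "notch", "ica_hook", "epoch",
                 "average_reference", "baseline", "reject"))
  expect_equal(ep$reference, "average")
  expect_equal(nrow(rejection_log(ep)), sum(ep$rejected))
})
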