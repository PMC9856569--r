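test_that("band-pass attenuation matches the analytic Butterworth response", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  cfg <- preprocess_config()
  for (f0 in c(10, 60, 90)) {
    x <- sin(2 * pi * f0 * t)
    rec <- new_recording(matrix(x, 1), fs)
    y <- bandpass(rec, cfg)$data[1, ]
    # zero-phase application squares the magnitude response
    expected <- butter_bp_mag2(f0, 0.5, 45, 3)
    core <- seq(2 * fs, length(t) - 2 * fs)  # avoid edge transients
    ratio <- sqrt(mean(y[core]^2) / mean(x[core]^2))
    expect_lt(abs(ratio - expected), 0.05)
  }
  # in-band tone essentially untouched, deep stop-band strongly attenuated
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(new_recording(matrix(x10, 1), fs), cfg)$data[1, ]
  expect_lt(abs(sqrt(mean(y10^2) / mean(x10^2)) - 1), 0.05)
  x90 <- sin(2 * pi * 90 * t)
  y90 <- bandpass(new_recording(matrix(x90, 1), fs), cfg)$data[1, ]
  expect_lt(sqrt(mean(y90^2) / mean(x90^2)), 0.02)
})

test_that("band-pass of the zero signal is zero and config is validated", {
  rec <- new_recording(matrix(0, 2, 5000), 500)
  expect_equal(bandpass(rec)$data, rec$data, ignore_attr = TRUE)
  expect_error(bandpass(toy_recording(fs = 80), preprocess_config(f_high = 45)),
               "Nyquist")
  expect_error(preprocess_config(f_low = 50, f_high = 45))
  expect_error(preprocess_config(window_s = 1, stride_s = 3))
})

test_that("channel rejection drops exactly the above-threshold channels", {
  set.seed(7)
  data <- matrix(rnorm(64 * 1000, sd = 20), 64, 1000)
  hot <- c(8, 12, 28, 34, 60)
  data[hot, ] <- data[hot, ] * 50
  rec <- new_recording(data, 500)
  out <- suppressMessages(reject_channels(rec, preprocess_config(amp_threshold = 200)))
  expect_equal(nrow(out$recording$data), 59)
  expect_setequal(out$rejected, rec$channel_labels[hot])
  # survivor order preserved
  expect_equal(out$recording$channel_labels, rec$channel_labels[-hot])

  # nothing above threshold: identity
  calm <- new_recording(matrix(rnorm(400), 4, 100), 500)
  out2 <- reject_channels(calm, preprocess_config(amp_threshold = 200))
  expect_identical(out2$recording$data, calm$data)
  expect_length(out2$rejected, 0)

  # degenerate threshold rejects everything -> fatal
  expect_error(preprocess_config(amp_threshold = 0), "positive")
  expect_error(suppressMessages(
    reject_channels(calm, preprocess_config(amp_threshold = 1e-9))), "all")
})

test_that("rejection and filtering commute with channel relabelling", {
  rec <- toy_recording(n_channels = 5, dur_s = 4)
  rec$data[2, ] <- rec$data[2, ] * 1000
  perm <- c(3, 1, 5, 2, 4)
  rec_p <- new_recording(rec$data[perm, ], rec$fs,
                         channel_labels = rec$channel_labels[perm])
  cfg <- preprocess_config(amp_threshold = 200)
  a <- suppressMessages(reject_channels(rec, cfg))
  b <- suppressMessages(reject_channels(rec_p, cfg))
  expect_setequal(a$rejected, b$rejected)
  expect_equal(a$recording$data[sort(a$recording$channel_labels), ],
               b$recording$data[sort(b$recording$channel_labels), ])
  fa <- bandpass(rec, cfg)
  fb <- bandpass(rec_p, cfg)
  expect_equal(fa$data[perm, ], fb$data, ignore_attr = TRUE)
})

test_that("window counts match brute-force enumeration and boundary cases", {
  expect_equal(count_windows(3600, 3, 1), 3598L)
  expect_equal(count_windows(3, 3, 1), 1L)
  expect_equal(count_windows(2.9, 3, 1), 0L)
  set.seed(1)
  for (i in 1:40) {
    dur <- runif(1, 1, 50)
    win <- runif(1, 0.5, 5)
    stride <- runif(1, 0.1, win)
    expect_equal(count_windows(dur, win, stride),
                 count_windows_oracle(dur, win, stride),
                 info = sprintf("dur=%g win=%g stride=%g", dur, win, stride))
  }
})

test_that("windowing yields complete, correctly timed, non-crossing windows", {
  rec <- toy_recording(n_channels = 2, fs = 100, dur_s = 10)
  cfg <- preprocess_config(window_s = 3, stride_s = 1)
  ws <- window_recording(rec, cfg)
  expect_length(ws$starts, 8)
  expect_equal(ws$n_window_samples, 300)
  expect_equal(diff(as.numeric(ws$timestamps)), rep(1, 7))
  blk <- window_block(ws, 3)
  expect_equal(dim(blk), c(2, 300))
  expect_equal(blk, rec$data[, 201:500], ignore_attr = TRUE)
  # exactly one window fits a window-length recording
  one <- window_recording(toy_recording(n_channels = 1, fs = 100, dur_s = 3), cfg)
  expect_length(one$starts, 1)
  expect_error(window_recording(toy_recording(n_channels = 1, fs = 100, dur_s = 2), cfg),
               "shorter")
  # windows of k files = sum of per-file counts (never cross files)
  expect_equal(24L * count_windows(3600, 3, 1), 86352L)
})

test_that("downsampling preserves duration, constants and sinusoid amplitude", {
  fs <- 500
  rec <- new_recording(matrix(sin(2 * pi * 5 * (0:1499) / fs), 1), fs)
  ds <- downsample(rec, 200)
  expect_equal(ncol(ds$data), 600)
  expect_equal(ds$fs, 200)
  # amplitude of the 5 Hz tone preserved within 2%
  # (interior stretch of 10 whole cycles, away from filter edge effects)
  core <- 101:500
  amp <- sqrt(2 * mean(ds$data[1, core]^2))
  expect_lt(abs(amp - 1), 0.02)

  const <- new_recording(matrix(2.5, 2, 1000), fs)
  dsc <- downsample(const, 200)
  expect_lt(max(abs(dsc$data[, 50:350] - 2.5)), 0.01)
  expect_error(downsample(rec, 500), "strictly below")
})
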