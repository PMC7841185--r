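# Conditioning chain: zero-phase band-pass, slicing-based epoching, baseline
# correction, decimation.

make_rec <- function(x, fs = 1200) recording(x, fs = fs, subject_id = "t")

test_that("band-pass preserves passband amplitude and kills the stopband", {
  fs <- 1200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  # 10 Hz sits deep in the passband: forward-backward |H|^2 within 2 %
  rec <- make_rec(sin(2 * pi * 10 * t))
  out <- bandpass_zero_phase(rec)
  core <- out$samples[(2 * fs):(8 * fs)]
  expect_lt(abs(max(core) - 1), 0.02)
  # 120 Hz is an octave above the 60 Hz edge: residual RMS < 5 %
  rec2 <- make_rec(sin(2 * pi * 120 * t))
  out2 <- bandpass_zero_phase(rec2)
  expect_lt(sd(out2$samples[(2 * fs):(8 * fs)]) / sd(rec2$samples), 0.05)
})

test_that("filtering is zero-phase: a symmetric pulse keeps its argmax", {
  fs <- 1200
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  pulse <- exp(-(t - 2)^2 / (2 * 0.02^2))
  out <- bandpass_zero_phase(make_rec(pulse))
  expect_lte(abs(which.max(out$samples) - which.max(pulse)), 1)
})

test_that("filter validates its preconditions", {
  expect_error(bandpass_zero_phase(make_rec(rnorm(100), fs = 100)),
               "twice the upper band edge")
  expect_error(bandpass_zero_phase(make_rec(rnorm(10))), "too short")
})

test_that("epoching is pure slicing with the documented index convention", {
  fs <- 1200
  onsets <- c(2, 5, 8)
  x <- numeric(10 * fs)
  # impulse exactly at each onset sample
  x[round(onsets * fs) + 1] <- 7
  rec <- make_rec(x)
  ev <- event_table(onset = onsets, duration = rep(0.75, 3),
                    trial_type = rep("target_8_12", 3))
  ep <- extract_epochs(rec, ev, "target_8_12", window = c(-0.3, 1.0))
  expect_identical(dim(ep$epochs), c(3L, as.integer(round(1.3 * fs))))
  t_axis <- epoch_times(ep)
  onset_col <- which(t_axis == 0)
  expect_identical(unname(ep$epochs[, onset_col]), rep(7, 3))
  expect_true(all(ep$epochs[, -onset_col] == 0))
  # epochs are verbatim slices of the recording
  k <- round((onsets[2] - 0.3) * fs)
  expect_identical(ep$epochs[2, ], rec$samples[(k + 1):(k + round(1.3 * fs))])
})

test_that("silent periods of the default schedule yield 100 epochs", {
  cfg <- cohort_config()
  ev <- generate_event_schedule(cfg, seed = 8)
  fs <- 100 # slicing only; low rate keeps the zero recording small
  rec <- make_rec(numeric(round((schedule_span(ev) + 2) * fs)), fs = fs)
  ep <- extract_epochs(rec, ev, "silent", window = c(-0.3, 1.0))
  expect_identical(nrow(ep$epochs), 100L)
})

test_that("out-of-bounds events abort with the offending onsets", {
  rec <- make_rec(numeric(1200))
  ev <- event_table(onset = c(0.5, 0.9), duration = c(0.75, 0.75),
                    trial_type = rep("target_8_12", 2))
  expect_error(extract_epochs(rec, ev, "target_8_12", window = c(-0.3, 1.0)),
               "0.9")
})

test_that("baseline correction zeroes the pre-onset mean", {
  fs <- 600
  n <- round(1.3 * fs)
  ep <- epoch_set(matrix(5, 2, n), fs = fs, window = c(-0.3, 1.0), "target_8_12")
  out <- baseline_correct(ep)
  expect_true(all(out$epochs == 0))

  set.seed(1)
  m <- matrix(rnorm(3 * n, mean = 3), 3, n)
  out2 <- baseline_correct(epoch_set(m, fs, c(-0.3, 1.0), "target_8_12"))
  t_axis <- epoch_times(out2)
  base_idx <- t_axis >= -0.3 & t_axis < 0
  expect_lt(max(abs(rowMeans(out2$epochs[, base_idx]))), 1e-12)

  # brute-force subtraction oracle on a linear ramp
  ramp <- matrix(seq_len(n), 1, n)
  out3 <- baseline_correct(epoch_set(ramp, fs, c(-0.3, 1.0), "target_8_12"))
  expect_equal(out3$epochs[1, ], ramp[1, ] - mean(ramp[1, base_idx]))

  short <- epoch_set(matrix(0, 1, round(1.1 * fs)), fs, c(-0.1, 1.0), "target_8_12")
  expect_error(baseline_correct(short), "not covered")
})

test_that("decimation keeps every factor-th sample from the first", {
  ep <- epoch_set(matrix(0:9, 1, 10), fs = 10, window = c(-0.5, 0.5), "silent")
  out <- downsample_epochs(ep, 2)
  expect_equal(out$epochs[1, ], c(0, 2, 4, 6, 8))
  expect_equal(out$fs, 5)
  expect_error(downsample_epochs(ep, 1.5), "positive integer")

  fs <- 1200
  n <- round(1.3 * fs)
  t_axis <- -0.3 + (0:(n - 1)) / fs
  sine <- matrix(sin(2 * pi * 10 * t_axis), 1, n)
  out2 <- downsample_epochs(epoch_set(sine, fs, c(-0.3, 1.0), "target_8_12"), 2)
  expect_identical(ncol(out2$epochs), 780L)
  t2 <- epoch_times(out2)
  expect_equal(out2$epochs[1, ], sin(2 * pi * 10 * t2), tolerance = 1e-9)
})

test_that("baseline before or after decimation agree on band-limited epochs", {
  # harmonics with whole periods inside the 0.3 s baseline, so the decimated
  # baseline mean equals the full-rate mean exactly
  fs <- 1200
  n <- round(1.3 * fs)
  t_axis <- -0.3 + (0:(n - 1)) / fs
  x <- matrix(2 * sin(2 * pi * 10 * t_axis) + cos(2 * pi * 40 * t_axis + 0.3), 1, n)
  ep <- epoch_set(x, fs, c(-0.3, 1.0), "target_8_12")
  a <- downsample_epochs(baseline_correct(ep), 2)
  b <- baseline_correct(downsample_epochs(ep, 2))
  expect_lt(max(abs(a$epochs - b$epochs)), 1e-9)
})

test_that("crop_epochs selects the half-open sub-window", {
  fs <- 600
  n <- round(1.3 * fs)
  ep <- epoch_set(matrix(seq_len(n), 1, n), fs, c(-0.3, 1.0), "target_8_12")
  cr <- crop_epochs(ep, 0, 1)
  expect_identical(ncol(cr$epochs), 600L)
  expect_equal(epoch_times(cr)[1], 0)
  expect_error(crop_epochs(ep, 2, 3), "no samples")
})
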