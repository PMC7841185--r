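# AEP averaging and peak feature extraction.

aep_from_values <- function(values, fs = 600, window = c(-0.3, 0.5)) {
  average_epochs(epoch_set(matrix(values, 1), fs, window, "target_8_12"))
}

pulse_values <- function(A, L, fs = 600, window = c(-0.3, 0.5), sigma = 0.02) {
  n <- round((window[2] - window[1]) * fs)
  t_axis <- window[1] + (0:(n - 1)) / fs
  A * exp(-(t_axis - L)^2 / (2 * sigma^2))
}

test_that("averaging is the pointwise mean and is linear", {
  n <- 480
  x <- sin(seq_len(n) / 20)
  ep <- epoch_set(rbind(x, x, x), 600, c(-0.3, 0.5), "target_8_12")
  expect_equal(average_epochs(ep)$values, x)

  ep2 <- epoch_set(rbind(x, -x), 600, c(-0.3, 0.5), "target_8_12")
  expect_true(all(average_epochs(ep2)$values == 0))

  alpha <- 2.5
  ep3 <- epoch_set(rbind(x, 2 * x) * alpha, 600, c(-0.3, 0.5), "target_8_12")
  expect_equal(average_epochs(ep3)$values, alpha * average_epochs(
    epoch_set(rbind(x, 2 * x), 600, c(-0.3, 0.5), "target_8_12"))$values)

  expect_error(average_epochs(epoch_set(matrix(0, 0, n), 600, c(-0.3, 0.5),
                                        "target_8_12")), "empty")
})

test_that("averaging suppresses noise at the standard-error rate", {
  set.seed(3)
  A <- 120; noise_sd <- 50; n_ep <- 100
  base <- pulse_values(A, 0.25)
  m <- matrix(rep(base, n_ep), n_ep, length(base), byrow = TRUE) +
    matrix(rnorm(n_ep * length(base), 0, noise_sd), n_ep)
  feats <- aep_features(epoch_set(m, 600, c(-0.3, 0.5), "target_8_12"))
  expect_lt(abs(feats$amplitude - A), 3 * noise_sd / sqrt(n_ep))
  expect_lt(abs(feats$latency - 0.25), 0.02)
})

test_that("peak amplitude is the signed post-onset maximum", {
  aep <- aep_from_values(pulse_values(71.4, 0.25))
  expect_equal(peak_amplitude(aep), 71.4, tolerance = 1e-6)

  # all-negative waveform: the (negative) maximum, not the largest deflection
  v <- -pulse_values(50, 0.25) - 5
  aep2 <- aep_from_values(v)
  expect_equal(peak_amplitude(aep2), max(v[seq(181 + 1, 480)]))
  expect_lt(peak_amplitude(aep2), 0)
  # absolute mode picks the big negative trough instead
  expect_equal(peak_amplitude(aep2, absolute = TRUE), min(v))

  # brute-force linear scan oracle on arbitrary data
  set.seed(11)
  v2 <- rnorm(480)
  aep3 <- aep_from_values(v2)
  t_axis <- -0.3 + (0:479) / 600
  expect_identical(peak_amplitude(aep3), max(v2[t_axis > 0]))
  expect_identical(peak_latency(aep3), t_axis[t_axis > 0][which.max(v2[t_axis > 0])])
})

test_that("peak latency uses the onset-to-peak convention with earliest-tie rule", {
  aep <- aep_from_values(pulse_values(100, 0.25))
  expect_lt(abs(peak_latency(aep) - 0.25), 1 / 600 + 1e-12)

  # peak at the first post-onset sample
  v <- numeric(480); v[182] <- 1 # t = 0 is sample 181 (0-based 180)
  expect_equal(peak_latency(aep_from_values(v)), 1 / 600)

  # plateau of two equal maxima: earlier sample wins
  v2 <- numeric(480); v2[c(200, 300)] <- 5
  expect_equal(peak_latency(aep_from_values(v2)), (200 - 181) / 600)
})

test_that("group-median AEP features are ordered by severity on a default cohort", {
  feats <- cohortC()$features
  med <- function(col) tapply(feats[[col]], feats$group, median)[
    c("control", "mild", "moderate", "severe")]
  amp <- med("amplitude"); lat <- med("latency")
  # amplitude decreases across the stroke grades, and the control group sits
  # well above severe; the control-vs-mild gap (13 uV against a control
  # dispersion of ~37 uV) is not an ordering the study's own data support
  expect_true(all(diff(amp[2:4]) < 0))
  expect_gt(amp[["control"]], amp[["severe"]])
  expect_true(all(diff(lat) > 0))
})
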