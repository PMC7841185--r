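# Synthetic cohort generator: determinism, calibration of the effect maps to
# the study's group medians, schedule construction, and signal-level ground
# truth recovery.

test_that("cohort sampling is deterministic and structurally valid", {
  cfg <- cohort_config()
  c1 <- sample_cohort(cfg, seed = 11)
  c2 <- sample_cohort(cfg, seed = 11)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 31L)
  expect_identical(as.integer(table(c1$group)[c("control", "mild", "moderate", "severe")]),
                   c(10L, 7L, 7L, 7L))
  # control <=> laser 0 mW <=> no lesion volume
  expect_true(all(is.na(c1$lesion_volume) == (c1$group == "control")))
  expect_true(all((c1$laser_mW == 0) == (c1$group == "control")))
  fr <- as.matrix(c1[, FRAC_COLS])
  expect_true(all(fr >= 0))
  expect_equal(rowSums(fr), rep(1, 31), tolerance = 1e-12)
  expect_true(all(c1$aep_amplitude > 0))
  expect_true(all(c1$aep_latency > 0 & c1$aep_latency < 0.5))
})

test_that("effect maps pass through the study's group medians", {
  m <- map_features(3.33)
  expect_equal(m$amplitude, 124, tolerance = 1.5)  # mild-group median ~124 uV
  expect_equal(m$latency, 0.20, tolerance = 0.005) # mild-group median 0.20 s
  m2 <- map_features(4.65)
  expect_equal(m2$fractions[["delta"]], 0.58, tolerance = 0.01)
  expect_equal(m2$latency, 0.27, tolerance = 0.005)
})

test_that("effect maps are monotone over the lesion-volume range", {
  grid <- seq(3.0, 5.0, by = 0.1)
  feats <- lapply(grid, map_features)
  amp <- vapply(feats, `[[`, numeric(1), "amplitude")
  lat <- vapply(feats, `[[`, numeric(1), "latency")
  dl <- vapply(feats, function(f) f$fractions[["delta"]], numeric(1))
  th <- vapply(feats, function(f) f$fractions[["theta"]], numeric(1))
  al <- vapply(feats, function(f) f$fractions[["alpha"]], numeric(1))
  expect_true(all(diff(amp) < 0))
  expect_true(all(diff(lat) > 0))
  expect_true(all(diff(dl) > 0))
  expect_true(all(diff(th) < 0))
  expect_true(all(diff(al) < 0))
})

test_that("lesion-volume distributions match the configured group medians", {
  maps <- effect_maps()
  set.seed(99)
  draws <- eegstroke:::rtruncnorm_pos(10000, maps$volume$median[["severe"]],
                                      maps$volume$sd[["severe"]])
  expect_lt(abs(median(draws) - 4.65), 0.05)
})

test_that("event schedule has exact counts, spacing, and span", {
  cfg <- cohort_config()
  ev <- generate_event_schedule(cfg, seed = 3)
  expect_identical(as.integer(table(ev$trial_type)[c("target_8_12", "fm_4_8",
                                                   "fm_8_4", "fm_12_8", "silent")]),
                   rep(100L, 5))
  # onset(k+1) = onset(k) + duration(k) + isi, exactly
  expect_equal(diff(ev$onset), head(ev$duration, -1) + 2.0, tolerance = 1e-12)
  # 100*(4*0.75 + 2.0) + 500*2.0 = 1500 s total
  expect_equal(schedule_span(ev), 1500)
  expect_gte(schedule_span(ev), 1000)
  expect_identical(generate_event_schedule(cfg, seed = 3)$onset, ev$onset)
})

test_that("a lone evoked pulse lands at onset + latency with height A", {
  cfg <- cohort_config(background = FALSE, noise_sd = 0)
  ev <- event_table(onset = 2.0, duration = 0.75, trial_type = "target_8_12")
  truth <- list(subject_id = "one", group = "severe",
                aep_amplitude = 120, aep_latency = 0.25)
  rec <- synthesize_recording(truth, ev, cfg, seed = 1)
  expect_equal(max(rec$samples), 120, tolerance = 1e-9)
  t_peak <- (which.max(rec$samples) - 1) / cfg$fs
  expect_lt(abs(t_peak - 2.25), 1 / cfg$fs + 1e-12)
})

test_that("recordings are bit-identical for identical config and seed", {
  cfg <- small_cfg(noise_sd = 2)
  cohort <- sample_cohort(cfg, seed = 4)
  ev <- generate_event_schedule(cfg, seed = 4)
  r1 <- synthesize_recording(cohort[12, ], ev, cfg, seed = 9)
  r2 <- synthesize_recording(cohort[12, ], ev, cfg, seed = 9)
  expect_identical(r1$samples, r2$samples)
})

test_that("pipeline recovers ground-truth AEP parameters on clean signals", {
  cfg <- small_cfg(background = FALSE, noise_sd = 0)
  cohort <- sample_cohort(cfg, seed = 21)[c(1, 15, 28), ]
  feats <- cohort_features(cohort, cfg, seed = 21, what = "aep")
  expect_lt(max(abs(feats$amplitude - cohort$aep_amplitude) / cohort$aep_amplitude), 0.02)
  expect_lt(max(abs(feats$latency - cohort$aep_latency)), 2 / 600)
})

test_that("an all-delta background measures as strongly delta-dominant", {
  # The Welch stage's 0.22 s Hamming sections smear sub-4 Hz power into the
  # theta bins, bounding the measurable delta share near 0.79 for any signal
  # concentrated below 4 Hz; the generated extreme must sit at that bound,
  # far above any realistic cohort value.
  cfg <- cohort_config(noise_sd = 0, evoked = FALSE, n_events_per_type = 10)
  ev <- generate_event_schedule(cfg, seed = 3)
  truth <- list(subject_id = "pure_delta", group = NA_character_,
                frac_delta = 1, frac_theta = 0, frac_alpha = 0, frac_beta = 0,
                silent_delta = 1, silent_theta = 0, silent_alpha = 0,
                silent_beta = 0, aep_amplitude = 0, aep_latency = 0.2)
  rec <- synthesize_recording(truth, ev, cfg, seed = 11)
  f <- subject_features(rec, ev, cfg, what = "spectral")
  expect_gte(f$RP_delta, 0.75)
  expect_identical(which.max(unlist(f[, RP_COLS])), c(RP_delta = 1L))
})

test_that("histological volume is area times thickness, summed", {
  expect_equal(lesion_volume_from_sections(c(1, 2, 3), 0.01), 0.06)
  expect_identical(lesion_volume_from_sections(numeric(0), 0.01), 0)
  expect_error(lesion_volume_from_sections(c(1, -1), 0.01), "non-negative")
  expect_error(lesion_volume_from_sections(c(1, 2), 0), "positive")
  # 400 sections of 1 mm^2 at 10 um: inside the moderate-group range
  v <- lesion_volume_from_sections(rep(1.0, 400), 0.010)
  expect_equal(v, 4.0)
  expect_lt(abs(v - 4.14), 0.3)
})

test_that("feature_table_from_truth is exact at zero noise and reproducible", {
  cohort <- sample_cohort(cohort_config(), seed = 6)
  t1 <- feature_table_from_truth(cohort, seed = 2)
  t2 <- feature_table_from_truth(cohort, seed = 2)
  expect_identical(t1, t2)
  expect_equal(t1$RP_delta, cohort$frac_delta)
  expect_equal(t1$amplitude, cohort$aep_amplitude)
  expect_equal(t1$latency, cohort$aep_latency)
  expect_equal(t1$DAR, cohort$frac_delta / cohort$frac_alpha)
})

test_that("regressing volume on a jitter-free delta fraction inverts the map", {
  maps <- effect_maps()
  for (nm in c("amplitude", "latency", "frac_delta", "frac_theta", "frac_alpha")) {
    maps$jitter[[nm]] <- c(control = 0, mild = 0, moderate = 0, severe = 0)
  }
  cfg <- cohort_config(maps = maps)
  cohort <- sample_cohort(cfg, seed = 13)
  stroke <- cohort[cohort$group != "control", ]
  tab <- feature_table_from_truth(stroke, seed = 13)
  fit <- fit_ols(tab["RP_delta"], tab$lesion_volume)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["RP_delta"]), 1 / 0.068, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), -0.263 / 0.068, tolerance = 1e-6)
})
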