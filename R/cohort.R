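# Synthetic cohort generation: ground-truth subjects whose auditory-evoked
# and spectral properties depend on a known lesion volume, so that every
# downstream stage of the pipeline can be validated against a known answer.

#' Default effect maps from lesion volume to EEG ground truth
#'
#' Affine maps fitted through the group medians of the study conditions:
#' amplitude decreases, latency and delta fraction increase, theta and alpha
#' fractions decrease with lesion volume (mm^3). Control subjects sit at
#' separate baselines rather than on the volume maps. Per-group jitter
#' standard deviations are derived from the printed interquartile ranges
#' (sd = IQR / 1.349) with the volume-map-induced variance subtracted, so the
#' generated dispersion matches the study's, not just its medians.
#'
#' @return a list of map coefficients (`c(intercept, slope)` per feature),
#'   control baselines, jitter SDs, and per-group lesion-volume distributions.
#' @export
effect_maps <- function() {
  list(
    # stimulus-condition maps: feature = intercept + slope * volume
    amplitude = c(intercept = 310, slope = -56),       # uV
    latency = c(intercept = 0.025, slope = 0.0525),    # s
    frac_delta = c(intercept = 0.263, slope = 0.068),
    frac_theta = c(intercept = 0.4414, slope = -0.04545),
    frac_alpha = c(intercept = 0.1252, slope = -0.00758),
    control = list(
      amplitude = 137.19, latency = 0.16,
      fractions = c(delta = 0.40, theta = 0.31, alpha = 0.14, beta = 0.17) / 1.02),
    # no-stimulation condition: common across groups (no lesion effect)
    silent_fractions = c(delta = 0.63, theta = 0.19, alpha = 0.08, beta = 0.08) / 0.98,
    jitter = list(
      amplitude = c(control = 37, mild = 17, moderate = 24, severe = 5),
      latency = c(control = 0.022, mild = 0.017, moderate = 0.014, severe = 0.019),
      frac_delta = c(control = 0.052, mild = 0.012, moderate = 0.014, severe = 0.026),
      frac_theta = c(control = 0.044, mild = 0.027, moderate = 0.022, severe = 0.020),
      frac_alpha = c(control = 0.015, mild = 0.022, moderate = 0.007, severe = 0.015),
      silent_fractions = c(delta = 0.05, theta = 0.015, alpha = 0.03)),
    volume = list(
      median = c(mild = 3.33, moderate = 4.14, severe = 4.65),
      sd = c(mild = 0.274, moderate = 0.082, severe = 0.215)))
}

GROUPS <- c("control", "mild", "moderate", "severe")
LASER_MW <- c(control = 0, mild = 5, moderate = 11, severe = 17)

clamp_fractions <- function(fr, floor = 0.01) {
  fr <- pmax(fr, floor)
  fr / sum(fr)
}

# Sampled ground-truth fractions are kept inside the measurement chain's
# gamut - profiles no signal could ever exhibit as measured fractions are
# invalid ground truth (same logic as clamping latency inside the epoch):
#  - the 0.22 s Hamming Welch sections bound the measured theta/delta band-
#    power ratio from below (~1/3 through the full chain with baseline
#    correction), so delta/theta is capped at 3.0;
#  - the evoked pulse's own alpha-band footprint bounds the measured alpha
#    share from below (~0.06 at the study's larger amplitudes), so the alpha
#    fraction is floored at 0.055.
DELTA_THETA_CAP <- 3.0
ALPHA_FLOOR <- 0.055

cap_slow_ratio <- function(fr, cap = DELTA_THETA_CAP) {
  if (fr[["alpha"]] < ALPHA_FLOOR) {
    short <- ALPHA_FLOOR - fr[["alpha"]]
    fr[["alpha"]] <- ALPHA_FLOOR
    # take the shortfall from the largest band to keep the sum at 1
    big <- names(which.max(fr[setdiff(names(fr), "alpha")]))
    fr[[big]] <- fr[[big]] - short
  }
  if (fr[["delta"]] / fr[["theta"]] > cap) {
    s <- fr[["delta"]] + fr[["theta"]]
    fr[["delta"]] <- s * cap / (1 + cap)
    fr[["theta"]] <- s / (1 + cap)
  }
  fr
}

#' Evaluate the effect maps at a lesion volume
#'
#' @param volume lesion volume in mm^3.
#' @param maps map list, default [effect_maps()].
#' @return list with `amplitude` (uV), `latency` (s), and `fractions`
#'   (delta/theta/alpha/beta, summing to 1).
#' @export
map_features <- function(volume, maps = effect_maps()) {
  aff <- function(cf, v) unname(cf[1] + cf[2] * v)
  fr <- c(delta = aff(maps$frac_delta, volume),
          theta = aff(maps$frac_theta, volume),
          alpha = aff(maps$frac_alpha, volume))
  fr <- c(fr, beta = unname(1 - sum(fr)))
  list(amplitude = aff(maps$amplitude, volume),
       latency = aff(maps$latency, volume),
       fractions = clamp_fractions(fr))
}

#' Cohort configuration
#'
#' Defaults are the study conditions: 10/7/7/7 subjects per group, 1200 Hz
#' sampling, 100 events per stimulus type at a 2 s inter-stimulus interval,
#' 750 ms tones and 2 s silent periods. `bg_rms` scales the coloured
#' background (approximately the square root of the total measured 1-30 Hz
#' band power, in uV); `noise_sd` is white measurement noise. `background`
#' and `evoked` toggle the two signal components for controlled experiments.
#'
#' @param ... overrides of the default fields (unknown names error).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_per_group = c(control = 10, mild = 7, moderate = 7, severe = 7),
    fs = 1200,
    n_events_per_type = 100,
    isi = 2.0,
    stim_duration = 0.75,
    silent_duration = 2.0,
    psd_window = c(-0.300, 1.000),
    aep_window = c(-0.300, 0.500),
    baseline_window = c(-0.300, 0),
    downsample_factor = 2,
    aep_width_sigma = 0.020,
    noise_sd = 5,
    bg_rms = 40,
    background = TRUE,
    evoked = TRUE,
    bandpass = c(0.05, 60),
    filter_order = 4,
    maps = effect_maps(),
    seed = 1)
  cfg <- modify_config(cfg, list(...))
  stopifnot(all(cfg$n_per_group >= 1), cfg$fs >= 2 * cfg$bandpass[2],
            cfg$n_events_per_type >= 1, cfg$isi > 0, cfg$aep_width_sigma > 0)
  structure(cfg, class = "cohort_config")
}

rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample a cohort of subjects with ground truth
#'
#' Lesion volumes are drawn per group from normal distributions centred on
#' the group medians (truncated at zero); evoked amplitude/latency and
#' stimulus-condition band fractions follow the effect maps plus per-group
#' jitter. Silent-condition fractions share one distribution across groups,
#' so the no-stimulation condition carries no lesion signal. Amplitudes are
#' floored at 5 uV and latencies clamped to [0.02, 0.45] s.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (default `config$seed`); fixed seed gives an
#'   identical cohort.
#' @return data frame, one row per subject: identifiers, `laser_mW`,
#'   `lesion_volume` (NA for controls), `aep_amplitude`, `aep_latency`,
#'   `frac_*` (stimulus condition) and `silent_*` fractions.
#' @export
sample_cohort <- function(config = cohort_config(), seed = config$seed) {
  set.seed(derive_seed(seed, "cohort"))
  maps <- config$maps
  rows <- list()
  abbrev <- c(control = "ctl", mild = "mild", moderate = "mod", severe = "sev")
  for (g in GROUPS) {
    n <- config$n_per_group[[g]]
    for (i in seq_len(n)) {
      if (g == "control") {
        vol <- NA_real_
        base <- list(amplitude = maps$control$amplitude,
                     latency = maps$control$latency,
                     fractions = clamp_fractions(maps$control$fractions))
      } else {
        vol <- rtruncnorm_pos(1, maps$volume$median[[g]], maps$volume$sd[[g]])
        base <- map_features(vol, maps)
      }
      amp <- max(5, base$amplitude + stats::rnorm(1, 0, maps$jitter$amplitude[[g]]))
      lat <- min(0.45, max(0.02, base$latency + stats::rnorm(1, 0, maps$jitter$latency[[g]])))
      fr <- base$fractions[c("delta", "theta", "alpha")] +
        stats::rnorm(3, 0, c(maps$jitter$frac_delta[[g]],
                             maps$jitter$frac_theta[[g]],
                             maps$jitter$frac_alpha[[g]]))
      fr <- cap_slow_ratio(clamp_fractions(c(fr, beta = unname(1 - sum(fr)))))
      sfr <- maps$silent_fractions[c("delta", "theta", "alpha")] +
        stats::rnorm(3, 0, maps$jitter$silent_fractions)
      sfr <- cap_slow_ratio(clamp_fractions(c(sfr, beta = unname(1 - sum(sfr)))))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("%s_%02d", abbrev[[g]], i),
        group = g, laser_mW = LASER_MW[[g]], lesion_volume = vol,
        aep_amplitude = amp, aep_latency = lat,
        frac_delta = fr[["delta"]], frac_theta = fr[["theta"]],
        frac_alpha = fr[["alpha"]], frac_beta = fr[["beta"]],
        silent_delta = sfr[["delta"]], silent_theta = sfr[["theta"]],
        silent_alpha = sfr[["alpha"]], silent_beta = sfr[["beta"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Lesion volume from histological sections
#'
#' Total infarct volume as the sum of per-section traced areas times the
#' slice thickness.
#'
#' @param areas numeric vector of section areas in mm^2 (all `>= 0`).
#' @param thickness slice thickness in mm (`> 0`), e.g. 0.010 for 10 um.
#' @return volume in mm^3 (0 for an empty `areas`).
#' @export
lesion_volume_from_sections <- function(areas, thickness) {
  if (any(areas < 0)) stop("section areas must be non-negative")
  if (!is.finite(thickness) || thickness <= 0) stop("slice thickness must be positive")
  sum(areas) * thickness
}

#' Feature table directly from ground truth
#'
#' Bypasses signal synthesis: emits the per-subject biomarkers (relative
#' powers, DAR, DTABR, amplitude, latency) straight from the sampled ground
#' truth, optionally with additive Gaussian noise. Used to exercise the
#' regression stages in isolation.
#'
#' @param cohort a [sample_cohort()] data frame.
#' @param noise_sd list with `fractions`, `amplitude`, `latency` noise SDs
#'   (all default 0; ratios are recomputed from the noisy fractions so the
#'   DAR/DTABR identities hold).
#' @param seed integer seed.
#' @return data frame with columns `subject_id`, `group`, `RP_delta`,
#'   `RP_theta`, `RP_alpha`, `RP_beta`, `DAR`, `DTABR`, `amplitude`,
#'   `latency`, `lesion_volume`.
#' @export
feature_table_from_truth <- function(cohort,
                                     noise_sd = list(fractions = 0, amplitude = 0, latency = 0),
                                     seed = 1) {
  set.seed(derive_seed(seed, "truth_features"))
  n <- nrow(cohort)
  fr <- as.matrix(cohort[, c("frac_delta", "frac_theta", "frac_alpha", "frac_beta")])
  if (noise_sd$fractions > 0) {
    fr <- fr + matrix(stats::rnorm(4 * n, 0, noise_sd$fractions), ncol = 4)
    fr <- t(apply(fr, 1, clamp_fractions))
  }
  amp <- cohort$aep_amplitude + stats::rnorm(n, 0, noise_sd$amplitude)
  lat <- cohort$aep_latency + stats::rnorm(n, 0, noise_sd$latency)
  data.frame(
    subject_id = cohort$subject_id, group = cohort$group,
    RP_delta = fr[, 1], RP_theta = fr[, 2], RP_alpha = fr[, 3], RP_beta = fr[, 4],
    DAR = fr[, 1] / fr[, 3],
    DTABR = (fr[, 1] + fr[, 2]) / (fr[, 3] + fr[, 4]),
    amplitude = amp, latency = lat,
    lesion_volume = cohort$lesion_volume,
    stringsAsFactors = FALSE)
}
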