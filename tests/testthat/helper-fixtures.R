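# Shared fixtures. The heavy full-scale synthetic cohorts are built once per
# test session and cached; everything is generated in code under fixed seeds.

fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# small configuration for fast unit tests (10 events per type, ~150 s signal)
small_cfg <- function(...) cohort_config(n_events_per_type = 10, ...)

FRAC_COLS <- c("frac_delta", "frac_theta", "frac_alpha", "frac_beta")
RP_COLS <- c("RP_delta", "RP_theta", "RP_alpha", "RP_beta")
SILENT_TRUTH_COLS <- c("silent_delta", "silent_theta", "silent_alpha", "silent_beta")
SILENT_RP_COLS <- c("silent_RP_delta", "silent_RP_theta", "silent_RP_alpha", "silent_RP_beta")
CANDIDATES <- c("RP_alpha", "RP_theta", "RP_delta", "DAR", "amplitude", "latency")

# study-scale cohorts (31 subjects, 100 events per type), cached
study_cohort <- function(cfg, seed = 42) sample_cohort(cfg, seed = seed)

# background off, no measurement noise: isolates the evoked pulse
cohortA <- function() get_fixture("cohortA", function() {
  cfg <- cohort_config(background = FALSE, noise_sd = 0)
  cohort <- study_cohort(cfg)
  feats <- cohort_features(cohort, cfg, seed = 42, what = "aep")
  list(cohort = cohort, features = feats, config = cfg)
})

# coloured background on, no measurement noise: spectral recovery
cohortB <- function() get_fixture("cohortB", function() {
  cfg <- cohort_config(noise_sd = 0)
  cohort <- study_cohort(cfg)
  feats <- cohort_features(cohort, cfg, seed = 42, what = "spectral")
  list(cohort = cohort, features = feats, config = cfg)
})

# full defaults: background, evoked pulses, measurement noise
cohortC <- function() get_fixture("cohortC", function() {
  cfg <- cohort_config()
  cohort <- study_cohort(cfg)
  feats <- cohort_features(cohort, cfg, seed = 42)
  list(cohort = cohort, features = feats, config = cfg)
})

# The published final four-predictor equation, used as the generative truth
# for regression-stage simulations (coefficients: RP_theta, RP_delta,
# latency s, amplitude uV, intercept; response in mm^3).
EQ_COEF <- c(RP_theta = -3.962, RP_delta = 3.217, latency = 6.186,
             amplitude = -0.006)
EQ_INTERCEPT <- 2.312

equation_response <- function(features) {
  EQ_INTERCEPT +
    as.matrix(features[, names(EQ_COEF)]) %*% EQ_COEF
}

# stroke-only feature table (n = 21) with realistic feature ranges drawn from
# the generator's ground truth, response generated from the printed equation
# plus Gaussian noise
make_equation_table <- function(seed, noise_sd = 0.1) {
  cohort <- sample_cohort(cohort_config(), seed = seed)
  cohort <- cohort[cohort$group != "control", ]
  tab <- feature_table_from_truth(cohort, seed = seed)
  set.seed(derive_seed(seed, "equation_noise"))
  tab$lesion_volume <- drop(equation_response(tab)) + rnorm(nrow(tab), 0, noise_sd)
  tab
}
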