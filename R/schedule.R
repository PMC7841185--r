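#' Generate the randomised stimulation schedule
#'
#' The four frequency-modulated tone types (750 ms) and the silent period
#' (2 s) are each presented `n_events_per_type` times in uniformly random
#' order with a fixed inter-stimulus interval, so
#' `onset[k+1] = onset[k] + duration[k] + isi`. The first onset sits one ISI
#' after recording start (pre-stimulus baseline and filter settling); with
#' the defaults (100 of each, 2 s ISI) the last event ends at exactly
#' `100 * (4 * 0.75 + 2.0) + 500 * 2.0 = 1500` s.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return an [event_table()] with `5 * n_events_per_type` rows.
#' @export
generate_event_schedule <- function(config = cohort_config(), seed = config$seed) {
  set.seed(derive_seed(seed, "schedule"))
  types <- rep(TRIAL_TYPES, each = config$n_events_per_type)
  types <- sample(types)
  durations <- ifelse(types == "silent", config$silent_duration, config$stim_duration)
  onsets <- config$isi + c(0, cumsum(durations[-length(durations)] + config$isi))
  event_table(onset = onsets, duration = durations, trial_type = types)
}

#' Total span of an event schedule
#'
#' @param ev an [event_table()].
#' @return end time of the last event in seconds.
#' @export
schedule_span <- function(ev) {
  validate_events(ev)
  max(ev$onset + ev$duration)
}
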