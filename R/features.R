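# Per-subject biomarker extraction: the full conditioning chain (band-pass ->
# epoch -> baseline -> decimate) followed by the spectral and evoked-potential
# feature stages, for the stimulus and silent conditions.

#' Extract the per-subject biomarkers from one recording
#'
#' Runs the conditioning chain on the continuous recording, then computes
#' relative band powers, DAR and DTABR from target-stimulus epochs and from
#' silent epochs, plus AEP peak amplitude and latency from the averaged
#' target epochs.
#'
#' @param rec an `eeg_recording`.
#' @param events the matching [event_table()].
#' @param config a [cohort_config()] (windows, band edges, filter settings).
#' @param what which feature families to compute: any of `"spectral"`,
#'   `"aep"`.
#' @param keep_waveform if `TRUE`, attach the averaged AEP waveform as the
#'   `"waveform"` attribute of the result.
#' @return a one-row data frame with columns `subject_id`, `group`,
#'   `RP_delta`, `RP_theta`, `RP_alpha`, `RP_beta`, `DAR`, `DTABR`,
#'   `amplitude`, `latency` and the `silent_*` spectral counterparts (NA for
#'   families not requested).
#' @export
subject_features <- function(rec, events, config = cohort_config(),
                             what = c("spectral", "aep"),
                             keep_waveform = FALSE) {
  what <- match.arg(what, several.ok = TRUE)
  filtered <- bandpass_zero_phase(rec, config$bandpass[1], config$bandpass[2],
                                  config$filter_order)
  prep <- function(trial_types, window) {
    ep <- extract_epochs(filtered, events, trial_types, window = window)
    ep <- baseline_correct(ep, config$baseline_window)
    downsample_epochs(ep, config$downsample_factor)
  }
  row <- data.frame(subject_id = rec$subject_id, group = rec$group,
                    RP_delta = NA_real_, RP_theta = NA_real_,
                    RP_alpha = NA_real_, RP_beta = NA_real_,
                    DAR = NA_real_, DTABR = NA_real_,
                    amplitude = NA_real_, latency = NA_real_,
                    silent_RP_delta = NA_real_, silent_RP_theta = NA_real_,
                    silent_RP_alpha = NA_real_, silent_RP_beta = NA_real_,
                    silent_DAR = NA_real_, silent_DTABR = NA_real_,
                    stringsAsFactors = FALSE)
  waveform <- NULL
  if ("spectral" %in% what) {
    stim <- spectral_features(prep("target_8_12", config$psd_window))
    sil <- spectral_features(prep("silent", config$psd_window))
    row$RP_delta <- stim$rp[["delta"]]; row$RP_theta <- stim$rp[["theta"]]
    row$RP_alpha <- stim$rp[["alpha"]]; row$RP_beta <- stim$rp[["beta"]]
    row$DAR <- stim$dar; row$DTABR <- stim$dtabr
    row$silent_RP_delta <- sil$rp[["delta"]]; row$silent_RP_theta <- sil$rp[["theta"]]
    row$silent_RP_alpha <- sil$rp[["alpha"]]; row$silent_RP_beta <- sil$rp[["beta"]]
    row$silent_DAR <- sil$dar; row$silent_DTABR <- sil$dtabr
  }
  if ("aep" %in% what) {
    feats <- aep_features(prep("target_8_12", config$aep_window))
    row$amplitude <- feats$amplitude
    row$latency <- feats$latency
    waveform <- feats$waveform
  }
  if (keep_waveform) attr(row, "waveform") <- waveform
  row
}

#' Simulate a cohort and extract its feature table
#'
#' For each subject of `cohort`: generate a randomised event schedule,
#' synthesize the recording, and extract the biomarkers. Per-subject seeds
#' are derived from `seed` and the subject id, so any one subject can be
#' regenerated in isolation.
#'
#' @param cohort a [sample_cohort()] data frame.
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @param what feature families, as in [subject_features()].
#' @param out_dir if non-NULL, write per-subject `events.tsv` (and, when
#'   `write_recordings`, the raw recording) into this directory.
#' @param write_recordings write each synthetic recording to `out_dir`.
#' @param recording_format `"csv_json"` or `"edf"`.
#' @param keep_waveforms collect the averaged AEP waveforms (returned as the
#'   `"waveforms"` attribute: one row per subject plus a `"waveform_times"`
#'   attribute).
#' @param progress print one line per subject.
#' @return feature data frame, one row per subject, joined with `group`,
#'   `laser_mW` and `lesion_volume` from the cohort.
#' @export
cohort_features <- function(cohort, config = cohort_config(), seed = config$seed,
                            what = c("spectral", "aep"),
                            out_dir = NULL, write_recordings = FALSE,
                            recording_format = c("csv_json", "edf"),
                            keep_waveforms = FALSE, progress = FALSE) {
  recording_format <- match.arg(recording_format)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(cohort))
  waveforms <- NULL
  wf_times <- NULL
  for (i in seq_len(nrow(cohort))) {
    truth <- cohort[i, ]
    id <- truth$subject_id
    events <- generate_event_schedule(config, seed = derive_seed(seed, paste0("schedule_", id)))
    rec <- synthesize_recording(truth, events, config,
                                seed = derive_seed(seed, paste0("synth_", id)))
    if (!is.null(out_dir)) {
      write_events(events, file.path(out_dir, paste0(id, "_events.tsv")))
      if (write_recordings) {
        ext <- if (recording_format == "edf") ".edf" else ".csv"
        write_recording(rec, file.path(out_dir, paste0(id, ext)),
                        format = recording_format)
      }
    }
    row <- subject_features(rec, events, config, what = what,
                            keep_waveform = keep_waveforms)
    if (keep_waveforms && !is.null(attr(row, "waveform"))) {
      wf <- attr(row, "waveform")
      if (is.null(waveforms)) {
        waveforms <- matrix(NA_real_, nrow(cohort), length(wf$values))
        wf_times <- wf$window[1] + (seq_along(wf$values) - 1) / wf$fs
      }
      waveforms[i, ] <- wf$values
    }
    row$laser_mW <- truth$laser_mW
    row$lesion_volume <- truth$lesion_volume
    rows[[i]] <- row
    if (progress) message(sprintf("[%d/%d] %s done", i, nrow(cohort), id))
  }
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "waveform") <- NULL; r }))
  if (keep_waveforms) {
    rownames(waveforms) <- cohort$subject_id
    attr(out, "waveforms") <- waveforms
    attr(out, "waveform_times") <- wf_times
  }
  out
}
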