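#' Single-channel EEG recording
#'
#' The pipeline's in-memory representation of one continuous epidural EEG
#' channel. Voltages are always stored in microvolts; readers convert on the
#' way in.
#'
#' @param samples numeric vector of voltages in uV.
#' @param fs sampling rate in Hz.
#' @param subject_id subject label.
#' @param group one of `"control"`, `"mild"`, `"moderate"`, `"severe"` (or
#'   `NA` for externally supplied data).
#' @param channel channel label; the study montage has a single epidural
#'   electrode over right primary auditory cortex, hence the default.
#' @param start_time time of the first sample in seconds (0 by convention).
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, subject_id = "subject", group = NA_character_,
                      channel = "A1-right", start_time = 0) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         group = as.character(group),
         channel = as.character(channel),
         fs = as.numeric(fs),
         samples = as.numeric(samples),
         start_time = as.numeric(start_time)),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' Validate an `eeg_recording`
#'
#' Checks the container invariants: positive sampling rate and finite samples.
#' @param rec an `eeg_recording`.
#' @return `rec`, invisibly; errors name the offending field.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop("not an 'eeg_recording' object")
  if (!is.finite(rec$fs) || rec$fs <= 0) {
    stop("invalid recording: 'fs' must be a positive number, got ", rec$fs)
  }
  if (length(rec$samples) == 0) stop("invalid recording: 'samples' is empty")
  if (!all(is.finite(rec$samples))) {
    stop("invalid recording: 'samples' contains non-finite values")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s] channel %s\n  %d samples @ %g Hz (%.1f s), range [%.2f, %.2f] uV\n",
              x$subject_id, x$group, x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs, min(x$samples), max(x$samples)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

# Trial types of the stimulation protocol: a target chirp (8->12 kHz), three
# distractor FM sweeps used to limit habituation, and silent periods.
TRIAL_TYPES <- c("target_8_12", "fm_4_8", "fm_8_4", "fm_12_8", "silent")
TONE_TYPES <- c("target_8_12", "fm_4_8", "fm_8_4", "fm_12_8")

#' Construct and validate an event table
#'
#' Events follow the BIDS events.tsv dialect: `onset` and `duration` in
#' seconds from recording start, plus a `trial_type` drawn from the protocol's
#' five conditions.
#'
#' @param onset numeric vector of onsets (s), strictly increasing.
#' @param duration numeric vector of durations (s).
#' @param trial_type character vector of trial types.
#' @return a `data.frame` with class `event_table`.
#' @export
event_table <- function(onset, duration, trial_type) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  ev
}

#' Validate an event table
#'
#' @param ev a data frame with columns `onset`, `duration`, `trial_type`.
#' @return `ev` invisibly; errors on unordered onsets, unknown trial types,
#'   or non-positive durations.
#' @export
validate_events <- function(ev) {
  req <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(req, names(ev))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(ev) > 1 && any(diff(ev$onset) <= 0)) {
    stop("event onsets must be strictly increasing")
  }
  bad <- setdiff(unique(ev$trial_type), TRIAL_TYPES)
  if (length(bad) > 0) {
    stop("unknown trial_type value(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(ev$onset)) || any(!is.finite(ev$duration)) || any(ev$duration <= 0)) {
    stop("event onsets/durations must be finite and durations positive")
  }
  invisible(ev)
}
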