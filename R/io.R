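# On-disk contracts: recordings as EDF or CSV + JSON sidecar, events as
# BIDS-style events.tsv, per-subject biomarker tables as CSV. Numeric text
# output uses 17 significant digits so that CSV/TSV round trips are
# bit-stable.

fmt_full <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

write_table_full <- function(df, path, sep) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt_full(out[[j]])
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a recording from disk
#'
#' Two formats are supported: EDF (`format = "edf"`), and a dependency-light
#' `csv_json` pair where `<path>` is a one-column CSV of samples (header
#' `sample_uV`) accompanied by a JSON sidecar `<path without .csv>.json`
#' carrying `fs`, `subject_id`, `group`, `channel` and `start_time`.
#'
#' @param path file path (`.edf` or `.csv`).
#' @param format `"edf"`, `"csv_json"`, or `"auto"` (by extension).
#' @return an `eeg_recording` with samples in uV.
#' @export
read_recording <- function(path, format = c("auto", "csv_json", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv_json"
  }
  if (format == "edf") return(read_edf(path))
  if (!file.exists(path)) stop("recording file not found: ", path)
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for ", path, " (expected ", sidecar, ")")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("fs", "subject_id", "channel")) {
    if (is.null(meta[[field]])) {
      stop("sidecar ", sidecar, " is missing required field '", field, "'")
    }
  }
  samples <- utils::read.csv(path)$sample_uV
  if (is.null(samples)) stop("CSV ", path, " has no 'sample_uV' column")
  if (!is.numeric(meta$fs) || meta$fs <= 0) {
    stop("sidecar field 'fs' must be a positive number, got ", meta$fs)
  }
  if (any(!is.finite(samples))) {
    stop("recording ", path, " contains non-finite samples")
  }
  recording(samples, fs = meta$fs, subject_id = meta$subject_id,
            group = meta$group %||% NA_character_, channel = meta$channel,
            start_time = meta$start_time %||% 0)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to disk
#'
#' @param rec an `eeg_recording`.
#' @param path output path; `.edf` writes EDF, `.csv` writes the CSV + JSON
#'   sidecar pair.
#' @param format `"auto"`, `"csv_json"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv_json", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv_json"
  }
  validate_recording(rec)
  if (format == "edf") return(write_edf(rec, path))
  df <- data.frame(sample_uV = rec$samples)
  write_table_full(df, path, sep = ",")
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               channel = rec$channel, fs = rec$fs,
               start_time = rec$start_time, unit = "uV")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BIDS-style events.tsv file
#'
#' @param path tab-separated file with header `onset`, `duration`,
#'   `trial_type`; onsets in seconds from recording start.
#' @return a validated [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  event_table(ev$onset, ev$duration, ev$trial_type)
}

#' Write an event table as events.tsv
#'
#' @param ev an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ev, path) {
  validate_events(ev)
  write_table_full(as.data.frame(ev)[c("onset", "duration", "trial_type")],
                   path, sep = "\t")
  invisible(path)
}

#' Write a per-subject biomarker table
#'
#' One row per subject; errors on duplicated `subject_id`. Numeric columns are
#' written with full precision so a read/write cycle is the identity.
#'
#' @param features data frame with a `subject_id` column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (!"subject_id" %in% names(features)) {
    stop("feature table must have a 'subject_id' column")
  }
  dup <- unique(features$subject_id[duplicated(features$subject_id)])
  if (length(dup) > 0) {
    stop("duplicate subject_id in feature table: ", paste(dup, collapse = ", "))
  }
  write_table_full(features, path, sep = ",")
  invisible(path)
}

#' Read a per-subject biomarker table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return a data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
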