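# Minimal European Data Format (EDF) I/O for one continuous signal.
#
# EDF stores a 256-byte ASCII header, one 256-byte ASCII header per signal,
# then data records of 16-bit little-endian integers that map linearly from
# the digital range onto the declared physical range. Only the subset needed
# here is implemented: a single channel, 1-second data records, no
# annotations. The exact sample count (EDF itself only knows whole records)
# is stashed in the reserved header field as "NSAMP=<n>" so that round trips
# are length-exact; files without that annotation are read to the full
# record boundary.

edf_pad <- function(x, width) {
  x <- as.character(x)[1]
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' The physical range is set to a symmetric integer envelope of the data, so
#' the 16-bit quantization step is `2 * ceiling(max(abs(samples))) / 65535`
#' microvolts. The sampling rate must be a whole number of samples per second
#' because 1-second data records are used.
#'
#' @param rec an [recording()] object (samples in uV).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  validate_recording(rec)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate, got fs = ", fs)
  }
  fs <- as.integer(round(fs))
  x <- rec$samples
  n <- length(x)
  n_rec <- ceiling(n / fs)

  pm <- max(1, ceiling(max(abs(x)) + 1e-9))
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (2 * pm) / (dig_max - dig_min)
  digital <- as.integer(round((x - (-pm)) / scale) + dig_min)
  digital <- pmin(pmax(digital, dig_min), dig_max)
  # zero-pad the trailing partial record at the digital code for 0 uV
  pad <- as.integer(round((0 + pm) / scale) + dig_min)
  digital <- c(digital, rep(pad, n_rec * fs - n))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste0("group=", rec$group), 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 + 256, 8),
    edf_pad(paste0("NSAMP=", n), 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(1, 4),
    # signal header
    edf_pad(rec$channel, 16),
    edf_pad("", 80),
    edf_pad("uV", 8),
    edf_num(-pm), edf_num(pm),
    edf_num(dig_min), edf_num(dig_max),
    edf_pad("", 80),
    edf_pad(fs, 8),
    edf_pad("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(digital, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Only single-signal continuous EDF files are supported. The physical
#' dimension is honoured and converted to microvolts (`V`, `mV`, `uV`
#' recognised).
#'
#' @param path EDF file path.
#' @return an `eeg_recording` with samples in uV.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  grab <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- grab(8)
  patient <- grab(80)
  rec_id <- grab(80)
  grab(8); grab(8) # start date / time, unused
  hdr_bytes <- suppressWarnings(as.integer(grab(8)))
  reserved <- grab(44)
  n_rec <- suppressWarnings(as.integer(grab(8)))
  rec_dur <- suppressWarnings(as.numeric(grab(8)))
  ns <- suppressWarnings(as.integer(grab(4)))
  if (is.na(hdr_bytes) || is.na(n_rec) || is.na(rec_dur) || is.na(ns)) {
    stop("unreadable EDF header in ", path, ": non-numeric size fields")
  }
  if (ns != 1) stop("unsupported EDF file: expected 1 signal, found ", ns)
  label <- grab(16)
  grab(80) # transducer
  phys_dim <- grab(8)
  phys_min <- suppressWarnings(as.numeric(grab(8)))
  phys_max <- suppressWarnings(as.numeric(grab(8)))
  dig_min <- suppressWarnings(as.numeric(grab(8)))
  dig_max <- suppressWarnings(as.numeric(grab(8)))
  grab(80) # prefiltering
  spr <- suppressWarnings(as.integer(grab(8)))
  grab(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) ||
      phys_max <= phys_min || dig_max <= dig_min) {
    stop("unreadable EDF header in ", path, ": bad physical/digital range fields")
  }

  digital <- readBin(con, "integer", n = n_rec * spr, size = 2,
                     signed = TRUE, endian = "little")
  if (length(digital) < n_rec * spr) {
    stop("EDF file truncated: expected ", n_rec * spr, " samples, read ", length(digital))
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  x <- (digital - dig_min) * scale + phys_min

  unit_factor <- switch(tolower(phys_dim),
                        "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
                        stop("unsupported EDF physical dimension '", phys_dim, "'"))
  x <- x * unit_factor

  nsamp <- if (grepl("^NSAMP=\\d+$", reserved)) {
    as.integer(sub("^NSAMP=", "", reserved))
  } else {
    length(x)
  }
  x <- x[seq_len(min(nsamp, length(x)))]

  group <- if (grepl("^group=", rec_id)) sub("^group=", "", rec_id) else NA_character_
  recording(x, fs = spr / rec_dur, subject_id = patient, group = group,
            channel = label)
}
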