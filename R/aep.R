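# Auditory evoked potential (AEP): average of target-stimulus epochs over
# the (-300 ms, 500 ms) window, and its peak amplitude / latency features.

#' Average epochs into an AEP waveform
#'
#' Pointwise mean across trials. Only target-type epochs should be averaged;
#' the three distractor FM sweeps are habituation controls.
#'
#' @param ep an `epoch_set` (baseline-corrected, typically at 600 Hz over
#'   `(-0.3, 0.5)` s).
#' @return an `aep_waveform`: list with `values`, `fs`, `window`, `n_epochs`.
#' @export
average_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  if (nrow(ep$epochs) == 0) stop("cannot average an empty epoch set")
  structure(list(values = colMeans(ep$epochs), fs = ep$fs, window = ep$window,
                 n_epochs = nrow(ep$epochs)),
            class = "aep_waveform")
}

#' @export
print.aep_waveform <- function(x, ...) {
  cat(sprintf("<aep_waveform> %d samples @ %g Hz over [%g, %g) s, mean of %d epochs\n",
              length(x$values), x$fs, x$window[1], x$window[2], x$n_epochs))
  invisible(x)
}

post_onset_index <- function(aep) {
  t <- aep$window[1] + (seq_along(aep$values) - 1) / aep$fs
  which(t > 0)
}

#' AEP peak amplitude
#'
#' The signed maximum voltage after stimulus onset (`t > 0`) - the highest
#' recorded voltage, not the largest magnitude. Amplitude is baseline-to-peak
#' because upstream baseline correction zeroes the pre-onset mean.
#'
#' @param aep an `aep_waveform` covering `(0, t_end]`.
#' @param absolute if `TRUE`, use the largest `abs()` deflection instead of
#'   the signed maximum (off by default).
#' @return amplitude in uV.
#' @export
peak_amplitude <- function(aep, absolute = FALSE) {
  stopifnot(inherits(aep, "aep_waveform"))
  v <- aep$values[post_onset_index(aep)]
  if (absolute) v[which.max(abs(v))] else max(v)
}

#' AEP peak latency
#'
#' Time from stimulus onset to the peak; ties are broken by the earliest
#' sample, so the returned latency is deterministic.
#'
#' @inheritParams peak_amplitude
#' @return latency in seconds (multiple of `1/fs`).
#' @export
peak_latency <- function(aep, absolute = FALSE) {
  stopifnot(inherits(aep, "aep_waveform"))
  idx <- post_onset_index(aep)
  v <- aep$values[idx]
  k <- if (absolute) which.max(abs(v)) else which.max(v)
  t <- aep$window[1] + (idx[k] - 1) / aep$fs
  t
}

#' Extract AEP features from target epochs
#'
#' @param ep baseline-corrected target-trial `epoch_set` over `(-0.3, 0.5)` s.
#' @param absolute passed to the peak pickers.
#' @return list with `amplitude` (uV), `latency` (s), and the `waveform`.
#' @export
aep_features <- function(ep, absolute = FALSE) {
  aep <- average_epochs(ep)
  list(amplitude = peak_amplitude(aep, absolute = absolute),
       latency = peak_latency(aep, absolute = absolute),
       waveform = aep)
}
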