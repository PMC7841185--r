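# Welch power spectral density and the spectral biomarkers: relative band
# powers over the four canonical bands, the delta/alpha ratio (DAR) and the
# (delta+theta)/(alpha+beta) ratio (DTABR).

#' Canonical EEG band scheme
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30 Hz. Band intervals are
#' half-open `[low, high)` so shared edges are never counted twice.
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

welch_one <- function(x, fs, L, step, w, nfft, scale_idx) {
  starts <- seq(1, length(x) - L + 1, by = step)
  U <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    p <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / (fs * U)
    acc <- acc + p
  }
  acc <- acc / length(starts)
  acc[scale_idx] <- 2 * acc[scale_idx] # one-sided: double all but DC/Nyquist
  acc
}

#' Welch power spectral density of an epoch set
#'
#' Each epoch is divided into `n_sections` sections of equal length with the
#' given fractional overlap, tapered with a Hamming window, and the
#' periodograms averaged; the per-epoch PSDs are then averaged across epochs.
#' Section length is `floor(2 N / (n_sections + 1))` (133 samples for the
#' 1-second, 600 Hz post-stimulus segment), and sections are zero-padded to
#' `nfft` (default 256, giving a 600/256 ~ 2.34 Hz grid in which every
#' canonical band keeps at least one bin).
#'
#' @param ep an `epoch_set`, typically cropped to the post-stimulus `[0, 1)` s.
#' @param n_sections number of Welch sections per epoch (default 8).
#' @param overlap fractional overlap between sections (default 0.5).
#' @param nfft FFT length; `NULL` picks `max(256, next power of two >= L)`.
#' @return a `psd_estimate`: list with `freqs` (Hz), `power` (uV^2/Hz),
#'   `n_epochs`, `fs`, `nfft`.
#' @export
welch_psd <- function(ep, n_sections = 8, overlap = 0.5, nfft = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  N <- ncol(ep$epochs)
  L <- floor(2 * N / (n_sections + 1))
  if (L < 8) {
    stop("epochs too short for ", n_sections, " Welch sections: N = ", N)
  }
  noverlap <- floor(L * overlap)
  step <- L - noverlap
  if (step < 1) stop("overlap too large: sections do not advance")
  if (is.null(nfft)) nfft <- max(256, 2^ceiling(log2(L)))
  w <- hamming_window(L)
  scale_idx <- 2:(nfft %/% 2 + if (nfft %% 2 == 0) 0 else 1)
  acc <- numeric(nfft %/% 2 + 1)
  for (i in seq_len(nrow(ep$epochs))) {
    acc <- acc + welch_one(ep$epochs[i, ], ep$fs, L, step, w, nfft, scale_idx)
  }
  structure(list(freqs = (0:(nfft %/% 2)) * ep$fs / nfft,
                 power = acc / nrow(ep$epochs),
                 n_epochs = nrow(ep$epochs), fs = ep$fs, nfft = nfft),
            class = "psd_estimate")
}

#' Absolute band power from a PSD estimate
#'
#' Sum of the PSD values at grid frequencies `f` with `low <= f < high`
#' (half-open; the 1 Hz floor of the delta band keeps DC out).
#'
#' @param psd a `psd_estimate`.
#' @param band `c(low, high)` in Hz.
#' @return summed power (uV^2 / Hz x bins).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"), length(band) == 2)
  idx <- psd$freqs >= band[1] & psd$freqs < band[2]
  if (!any(idx)) {
    stop("band [", band[1], ", ", band[2], ") Hz contains no PSD grid points")
  }
  sum(psd$power[idx])
}

#' Relative band powers
#'
#' Each band's absolute power divided by the total over the four defined
#' bands only (1-30 Hz): content below 1 Hz and above 30 Hz is excluded from
#' the normalisation.
#'
#' @param psd a `psd_estimate`.
#' @param scheme band scheme, default [eeg_bands()].
#' @return named numeric vector of relative powers summing to 1.
#' @export
relative_powers <- function(psd, scheme = eeg_bands()) {
  powers <- vapply(scheme, function(b) band_power(psd, b), numeric(1))
  total <- sum(powers)
  if (total <= 0) stop("total band power is zero; relative powers undefined")
  powers / total
}

#' Slow/fast ratios DAR and DTABR
#'
#' `DAR = RP_delta / RP_alpha`, `DTABR = (RP_delta + RP_theta) /
#' (RP_alpha + RP_beta)`, from relative (equivalently absolute) band powers.
#'
#' @param rp named vector with `delta`, `theta`, `alpha`, `beta` entries.
#' @return named vector `c(dar, dtabr)`.
#' @export
band_ratios <- function(rp) {
  stopifnot(all(c("delta", "theta", "alpha", "beta") %in% names(rp)))
  if (rp[["alpha"]] <= 0) stop("DAR undefined: alpha power is zero")
  if (rp[["alpha"]] + rp[["beta"]] <= 0) stop("DTABR undefined: alpha + beta power is zero")
  c(dar = rp[["delta"]] / rp[["alpha"]],
    dtabr = (rp[["delta"]] + rp[["theta"]]) / (rp[["alpha"]] + rp[["beta"]]))
}

#' Spectral biomarkers of an epoch set
#'
#' Convenience wrapper: Welch PSD on the post-stimulus `[0, 1)` s segment,
#' then relative powers and ratios.
#'
#' @param ep an `epoch_set` covering at least `[0, 1)` s.
#' @param scheme band scheme.
#' @param ... passed to [welch_psd()].
#' @return list with `rp` (named vector), `dar`, `dtabr`, and the `psd`.
#' @export
spectral_features <- function(ep, scheme = eeg_bands(), ...) {
  psd <- welch_psd(crop_epochs(ep, 0, 1), ...)
  rp <- relative_powers(psd, scheme)
  ratios <- band_ratios(rp)
  list(rp = rp, dar = unname(ratios["dar"]), dtabr = unname(ratios["dtabr"]),
       psd = psd)
}
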