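#' Derive a reproducible child seed from a master seed and a label
#'
#' Stages of the pipeline (cohort sampling, per-subject schedules, signal
#' synthesis, split validation) each draw from their own RNG stream so that a
#' single master seed reproduces the whole run while any one stage can be
#' re-run in isolation. The child seed is a 31-bit hash of the label mixed
#' with the master seed; all arithmetic stays below 2^53 so the computation is
#' exact in doubles.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the stream.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.character(label), length(label) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Modify a nested list of defaults
#'
#' Recursive version of [utils::modifyList()] that errors on names absent from
#' the defaults, so misspelled configuration fields fail loudly.
#' @noRd
modify_config <- function(defaults, overrides, path = "") {
  if (length(overrides) == 0) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  for (nm in nms) {
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown configuration field '%s%s'", path, nm), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- modify_config(defaults[[nm]], overrides[[nm]],
                                      path = paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}
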