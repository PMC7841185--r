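# Regression machinery for lesion-volume prediction: OLS with the reporting
# conventions of the study (unstandardized B, SE, standardized beta, R^2,
# population-form RMSE, rank-order AIC/BIC), the all-subsets search,
# collinearity diagnostics (tolerance/VIF), SPSS-style stepwise selection by
# probability-of-F thresholds, and prediction from a serialized final model.

as_design <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 1) stop("need at least one predictor column")
  if (!all(vapply(X, is.numeric, logical(1)))) stop("predictors must be numeric")
  as.matrix(X)
}

#' Ordinary least squares with study-style reporting
#'
#' Least squares with intercept via QR. Reports unstandardized coefficients
#' with classical standard errors, standardized betas
#' (`B_j * sd(x_j) / sd(y)`), `R^2 = 1 - SSE/SST`, RMSE as the population
#' standard deviation of the residuals (`sqrt(SSE/n)`; the residual mean is 0
#' in an intercept model), and Gaussian-likelihood
#' `AIC = n log(SSE/n) + 2(k+1)`, `BIC = n log(SSE/n) + (k+1) log(n)` whose
#' additive constants are dropped - only rank order across models on the same
#' data is meaningful. A perfect fit (SSE = 0) reports `-Inf` for both, which
#' preserves the ordering contract.
#'
#' @param X data frame or matrix of predictor columns (no intercept column).
#' @param y numeric response (lesion volume, mm^3).
#' @return an object of class `ols_fit`: `coefficients` (named, with
#'   `(Intercept)`), `se`, `beta_std`, `t`, `p`, `r2`, `rmse`, `aic`, `bic`,
#'   `residuals`, `fitted`, `sigma2`, `n`, `k`, `predictors`.
#' @export
fit_ols <- function(X, y) {
  X <- as_design(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions differ")
  k <- ncol(X)
  if (n <= k + 1) stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")")
  mm <- cbind("(Intercept)" = 1, X)
  fit <- stats::lm.fit(mm, y)
  if (fit$rank < ncol(mm)) {
    aliased <- colnames(mm)[fit$qr$pivot[(fit$rank + 1):ncol(mm)]]
    stop("singular design: column(s) ", paste(aliased, collapse = ", "),
         " are linearly dependent on the others")
  }
  coefs <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  dfres <- n - k - 1
  sigma2 <- sse / dfres
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  xtx_inv <- chol2inv(R)
  piv <- fit$qr$pivot
  xtx_inv[piv, piv] <- xtx_inv
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(mm)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
  sdy <- stats::sd(y)
  beta_std <- coefs[-1] * apply(X, 2, stats::sd) / sdy
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  # numerically exact fit: SSE at rounding-noise level relative to the data
  exact <- sse <= 1e-20 * max(1, sum(y^2))
  ll_term <- if (exact) -Inf else n * log(sse / n)
  structure(list(
    coefficients = coefs, se = se, beta_std = beta_std, t = tval, p = pval,
    r2 = r2, rmse = sqrt(sse / n),
    aic = ll_term + 2 * (k + 1), bic = ll_term + (k + 1) * log(n),
    residuals = res, fitted = fit$fitted.values, sigma2 = sigma2,
    n = n, k = k, predictors = colnames(X)),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d, k = %d, R^2 = %.4f, RMSE = %.4f\n",
              x$n, x$k, x$r2, x$rmse))
  tab <- data.frame(B = x$coefficients, SE = x$se,
                    beta = c(NA, x$beta_std), t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Root mean square error (population form)
#'
#' `sqrt(mean((observed - predicted)^2))` - for an intercept model this
#' equals the standard deviation of the residuals, since their mean is zero.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return RMSE, in the units of the response (mm^3).
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ")
  }
  if (length(observed) == 0) stop("need at least one observation")
  sqrt(mean((observed - predicted)^2))
}

#' Information criteria of a fitted model
#'
#' @param fit an `ols_fit`.
#' @return named vector `c(aic, bic)` (see [fit_ols()] for the forms used).
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  c(aic = fit$aic, bic = fit$bic)
}

#' All-subsets regression
#'
#' Fits one model per non-empty predictor subset (`2^k - 1` models) and
#' ranks them by training RMSE; AIC/BIC accompany each row. With the study's
#' six selected predictors this is the 63-model search.
#'
#' @param X data frame of candidate predictors (`1 <= k <= 20`).
#' @param y numeric response.
#' @param best_per_size also compute the best `best_per_size` models for each
#'   subset size (attribute `"best_per_size"`; the study plots the best 3).
#' @return data frame, one row per subset, columns `predictors`
#'   (`+`-collapsed), `k`, `rmse`, `r2`, `aic`, `bic`, ranked by `rmse`.
#' @export
all_subsets <- function(X, y, best_per_size = 3) {
  X <- as.data.frame(X)
  k <- ncol(X)
  if (k < 1 || k > 20) stop("all-subsets search supports 1 to 20 predictors, got ", k)
  rows <- list()
  for (size in seq_len(k)) {
    combos <- utils::combn(names(X), size, simplify = FALSE)
    for (vars in combos) {
      fit <- fit_ols(X[vars], y)
      rows[[length(rows) + 1]] <- data.frame(
        predictors = paste(vars, collapse = "+"), k = size,
        rmse = fit$rmse, r2 = fit$r2, aic = fit$aic, bic = fit$bic,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$rmse), ]
  rownames(out) <- NULL
  best <- do.call(rbind, lapply(split(out, out$k), function(d)
    utils::head(d[order(d$rmse), ], best_per_size)))
  rownames(best) <- NULL
  attr(out, "best_per_size") <- best
  out
}

#' Collinearity diagnostics: tolerance and VIF
#'
#' For each predictor, `tolerance = 1 - R^2` of that predictor regressed on
#' all the others and `VIF = 1/tolerance`. Perfectly collinear predictors
#' report tolerance 0 and infinite VIF.
#'
#' @param X data frame or matrix of predictors (`n > k`).
#' @return data frame with `predictor`, `tolerance`, `vif`.
#' @export
collinearity <- function(X) {
  X <- as_design(X)
  if (nrow(X) <= ncol(X)) stop("need more observations than predictors")
  out <- lapply(seq_len(ncol(X)), function(j) {
    tol <- if (ncol(X) == 1) 1 else {
      others <- cbind(1, X[, -j, drop = FALSE])
      res <- stats::lm.fit(others, X[, j])$residuals
      sst <- sum((X[, j] - mean(X[, j]))^2)
      if (sst <= 0) 0 else max(0, sum(res^2) / sst)
    }
    if (tol < 1e-12) tol <- 0 # numerically perfect collinearity
    data.frame(predictor = colnames(X)[j], tolerance = tol,
               vif = if (tol > 0) 1 / tol else Inf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

partial_p <- function(X, y, vars, var) {
  fit <- fit_ols(X[c(vars, var)], y)
  unname(fit$p[var])
}

#' Stepwise linear regression (probability-of-F entry/removal)
#'
#' SPSS-style stepwise selection: at each step the candidate with the
#' smallest partial-F p value enters if below `p_enter`; after each entry,
#' any included variable whose p exceeds `p_remove` is removed (worst
#' first); the loop stops when no change occurs. Candidates whose tolerance
#' against the included set falls below `tol_min` are barred from entry, so
#' exactly one of a perfectly collinear pair can enter. The partial-F test
#' for a single variable is the squared t test of its coefficient, so t-test
#' p values are used directly.
#'
#' @param X data frame of candidate predictors.
#' @param y numeric response.
#' @param p_enter entry threshold on the partial-F p value (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param tol_min minimum entry tolerance (default 1e-4, the SPSS guard).
#' @return a `stepwise_trace`: list with `steps` (data frame: step, action,
#'   variable, r2, rmse), `fits` (per-step `ols_fit`s), `final` (final
#'   `ols_fit`, or NULL if nothing entered), `selected`, and `excluded`
#'   (collinearity stats of the non-selected candidates against the final
#'   model's predictors plus themselves).
#' @export
stepwise <- function(X, y, p_enter = 0.05, p_remove = 0.10, tol_min = 1e-4) {
  X <- as.data.frame(X)
  included <- character(0)
  steps <- list()
  fits <- list()
  repeat {
    changed <- FALSE
    # a numerically exact fit leaves no residual signal: entry p values
    # would be rounding noise
    if (length(included) > 0 && isTRUE(fit_ols(X[included], y)$r2 > 1 - 1e-12)) break
    candidates <- setdiff(names(X), included)
    if (length(candidates) > 0) {
      pvals <- vapply(candidates, function(v) {
        if (length(included) > 0) {
          tol <- collinearity(X[c(included, v)])
          if (tol$tolerance[tol$predictor == v] < tol_min) return(NA_real_)
        }
        tryCatch(partial_p(X, y, included, v), error = function(e) NA_real_)
      }, numeric(1))
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < p_enter) {
        best <- candidates[which.min(pvals)]
        included <- c(included, best)
        fit <- fit_ols(X[included], y)
        steps[[length(steps) + 1]] <- data.frame(
          step = length(steps) + 1, action = "enter", variable = best,
          r2 = fit$r2, rmse = fit$rmse, stringsAsFactors = FALSE)
        fits[[length(steps)]] <- fit
        changed <- TRUE
      }
    }
    # removal phase: drop the worst included variable while any exceeds p_remove
    while (length(included) > 1) {
      fit <- fit_ols(X[included], y)
      pin <- fit$p[included]
      worst <- names(which.max(pin))
      if (pin[worst] <= p_remove) break
      included <- setdiff(included, worst)
      fit <- fit_ols(X[included], y)
      steps[[length(steps) + 1]] <- data.frame(
        step = length(steps) + 1, action = "remove", variable = worst,
        r2 = fit$r2, rmse = fit$rmse, stringsAsFactors = FALSE)
      fits[[length(steps)]] <- fit
      changed <- TRUE
    }
    if (!changed || length(steps) > 2 * ncol(X) + 10) break
  }
  final <- if (length(included) > 0) fit_ols(X[included], y) else NULL
  excluded_vars <- setdiff(names(X), included)
  excluded <- if (length(excluded_vars) > 0 && length(included) > 0) {
    do.call(rbind, lapply(excluded_vars, function(v) {
      cc <- collinearity(X[c(included, v)])
      cc[cc$predictor == v, ]
    }))
  } else {
    data.frame(predictor = excluded_vars,
               tolerance = rep(1, length(excluded_vars)),
               vif = rep(1, length(excluded_vars)), stringsAsFactors = FALSE)
  }
  structure(list(
    steps = if (length(steps) > 0) do.call(rbind, steps) else
      data.frame(step = integer(), action = character(), variable = character(),
                 r2 = numeric(), rmse = numeric()),
    fits = fits, final = final, selected = included, excluded = excluded),
    class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("<stepwise_trace>\n")
  if (nrow(x$steps) == 0) {
    cat("  no variable met the entry criterion\n")
  } else {
    print(x$steps)
    cat("final model:\n")
    print(x$final)
  }
  invisible(x)
}

#' Predict lesion volume from a (serialized) model
#'
#' Affine evaluation of a fitted model on new feature rows. Units follow the
#' training table: relative powers dimensionless, latency in seconds,
#' amplitude in uV; output in mm^3.
#'
#' @param model an `ols_fit`, a [read_model()] result, or any list with a
#'   named `coefficients` vector including `(Intercept)`.
#' @param features data frame containing every model feature as a column.
#' @return numeric vector of predicted volumes, one per row of `features`.
#' @export
predict_volume <- function(model, features) {
  coefs <- model$coefficients
  vars <- setdiff(names(coefs), "(Intercept)")
  missing_vars <- setdiff(vars, names(features))
  if (length(missing_vars) > 0) {
    stop("feature(s) missing from input: ", paste(missing_vars, collapse = ", "))
  }
  out <- rep(coefs[["(Intercept)"]], nrow(as.data.frame(features)))
  for (v in vars) out <- out + coefs[[v]] * features[[v]]
  unname(out)
}

#' Serialize a fitted model to JSON / read it back
#'
#' @param fit an `ols_fit`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a model list usable by
#'   [predict_volume()] (read).
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "ols_fit"))
  jsonlite::write_json(list(
    coefficients = as.list(fit$coefficients), se = as.list(fit$se),
    r2 = fit$r2, rmse = fit$rmse, n = fit$n, k = fit$k,
    predictors = fit$predictors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$se <- unlist(m$se)
  m
}

#' Univariate regression table
#'
#' One simple regression of the response on each predictor, with the study's
#' reporting columns (B, SE, standardized beta, R^2, p, Bonferroni-corrected
#' p across the `m` regressions).
#'
#' @param X data frame of predictors.
#' @param y numeric response.
#' @param m Bonferroni multiplier (defaults to `ncol(X)`).
#' @return data frame with one row per predictor.
#' @export
univariate_regressions <- function(X, y, m = ncol(X)) {
  X <- as.data.frame(X)
  rows <- lapply(names(X), function(v) {
    fit <- fit_ols(X[v], y)
    data.frame(predictor = v, B = unname(fit$coefficients[v]),
               SE = unname(fit$se[v]), beta = unname(fit$beta_std[v]),
               r2 = fit$r2, rmse = fit$rmse, p = unname(fit$p[v]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p, m)
  out
}
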