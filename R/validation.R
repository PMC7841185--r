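# Repeated random-split generalization experiment: hold out n_test subjects,
# run the full stepwise selection on the remaining training rows, score the
# held-out RMSE, repeat; report the RMSE distribution and how often each
# candidate is selected.

#' Repeated random train/test split evaluation
#'
#' Each iteration draws a uniform random test subset without replacement
#' (optionally stratified by a grouping column), runs stepwise selection on
#' the training rows, and computes the RMSE of the fitted model's predictions
#' on the held-out rows (the training-set mean is used when no variable
#' enters). One master seed spawns an independent per-iteration seed stream,
#' so iteration `i` is reproducible in isolation.
#'
#' @param table feature data frame (stroke subjects only).
#' @param predictors candidate predictor column names.
#' @param response response column (default `"lesion_volume"`).
#' @param n_test held-out subjects per iteration (default 3, as in an
#'   18/3 split of 21).
#' @param iters number of iterations (default 1000).
#' @param p_enter,p_remove stepwise thresholds.
#' @param seed master integer seed.
#' @param stratify_col optional grouping column for stratified test draws
#'   (off by default; draws are simply uniform).
#' @return a `split_eval`: list with `rmse` (length `iters`), `selected`
#'   (iters x predictors logical matrix), `frequency` (per-predictor
#'   selection frequency), `n_test`, `iter_seeds`.
#' @export
repeated_split_eval <- function(table, predictors,
                                response = "lesion_volume",
                                n_test = 3, iters = 1000,
                                p_enter = 0.05, p_remove = 0.10,
                                seed = 1, stratify_col = NULL) {
  table <- as.data.frame(table)
  n <- nrow(table)
  k <- length(predictors)
  if (n < n_test + k + 2) {
    stop("infeasible split: need at least n_test + k + 2 = ", n_test + k + 2,
         " rows, got ", n)
  }
  missing_cols <- setdiff(c(predictors, response), names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  set.seed(derive_seed(seed, "split_eval"))
  iter_seeds <- sample.int(2147483646L, iters)
  rmse_vec <- numeric(iters)
  selected <- matrix(FALSE, iters, k, dimnames = list(NULL, predictors))
  for (i in seq_len(iters)) {
    set.seed(iter_seeds[i])
    test_idx <- if (is.null(stratify_col)) {
      sample.int(n, n_test)
    } else {
      stratified_sample(table[[stratify_col]], n_test)
    }
    train <- table[-test_idx, , drop = FALSE]
    test <- table[test_idx, , drop = FALSE]
    tr <- stepwise(train[predictors], train[[response]],
                   p_enter = p_enter, p_remove = p_remove)
    pred <- if (is.null(tr$final)) {
      rep(mean(train[[response]]), nrow(test))
    } else {
      selected[i, tr$selected] <- TRUE
      predict_volume(tr$final, test)
    }
    rmse_vec[i] <- rmse(test[[response]], pred)
  }
  structure(list(rmse = rmse_vec, selected = selected,
                 frequency = colMeans(selected), n_test = n_test,
                 iter_seeds = iter_seeds),
            class = "split_eval")
}

stratified_sample <- function(groups, n_test) {
  tab <- table(groups)
  share <- n_test * as.numeric(tab) / length(groups)
  base <- floor(share)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  idx <- integer(0)
  for (gi in seq_along(tab)) {
    pool <- which(groups == names(tab)[gi])
    if (base[gi] > 0) idx <- c(idx, sample(pool, base[gi]))
  }
  idx
}

#' Summarize a split evaluation
#'
#' @param eval a `split_eval`.
#' @return list with `median_rmse`, `iqr_rmse`, `quartiles`, `frequency`
#'   (sorted, descending), `n_iter`.
#' @export
summarize_split_eval <- function(eval) {
  stopifnot(inherits(eval, "split_eval"))
  if (length(eval$rmse) == 0) stop("empty split evaluation")
  q <- stats::quantile(eval$rmse, c(0.25, 0.5, 0.75), names = FALSE)
  list(median_rmse = q[2], iqr_rmse = q[3] - q[1],
       quartiles = q, frequency = sort(eval$frequency, decreasing = TRUE),
       n_iter = length(eval$rmse))
}

#' @export
print.split_eval <- function(x, ...) {
  s <- summarize_split_eval(x)
  cat(sprintf("<split_eval> %d iterations, n_test = %d\n  test RMSE median %.4f (IQR %.4f)\n",
              s$n_iter, x$n_test, s$median_rmse, s$iqr_rmse))
  cat("  selection frequency:\n")
  print(round(s$frequency, 3))
  invisible(x)
}
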