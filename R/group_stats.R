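# Nonparametric group comparisons: Kruskal-Wallis omnibus tests, pairwise
# Mann-Whitney post-hocs with Bonferroni correction, and Shapiro-Wilk
# normality checks for regression residuals.

#' Kruskal-Wallis rank test across groups
#'
#' Thin, validated wrapper around [stats::kruskal.test()] (rank-based H with
#' tie correction, p from the chi-square approximation). The degenerate
#' all-identical case is defined as H = 0, p = 1.
#'
#' @param samples list of numeric vectors, one per group.
#' @return list with `statistic` (H), `df` (`n_groups - 1`), `p`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2 || any(lengths(samples) < 1)) {
    stop("need at least two non-empty groups")
  }
  pooled <- unlist(samples)
  if (length(unique(pooled)) == 1) {
    return(list(statistic = 0, df = length(samples) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(samples)
  list(statistic = unname(kt$statistic), df = as.integer(kt$parameter),
       p = kt$p.value)
}

#' Bonferroni correction
#'
#' @param p raw p value(s) in `[0, 1]`.
#' @param m number of tests (`>= 1`).
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  if (m < 1) stop("number of tests must be >= 1")
  pmin(1, p * m)
}

#' All pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Intended as the post-hoc after a significant Kruskal-Wallis omnibus test
#' (set `check_omnibus = FALSE` to run unconditionally). Uses the exact
#' distribution for small tie-free groups (both n <= 8) and the normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param samples named list of numeric group vectors.
#' @param n_tests Bonferroni multiplier; defaults to the number of pairs.
#' @param check_omnibus require Kruskal-Wallis `p < alpha` first.
#' @param alpha omnibus significance level (default 0.05).
#' @return data frame with one row per pair: `group1`, `group2`, `U`,
#'   `p`, `p_bonf`.
#' @export
pairwise_mannwhitney <- function(samples, n_tests = NULL,
                                 check_omnibus = FALSE, alpha = 0.05) {
  if (any(lengths(samples) == 0)) stop("empty group in pairwise comparisons")
  if (is.null(names(samples))) names(samples) <- paste0("group", seq_along(samples))
  if (check_omnibus) {
    omni <- kruskal_wallis(samples)
    if (omni$p >= alpha) {
      stop("omnibus Kruskal-Wallis not significant (p = ",
           format(omni$p, digits = 3), "); post-hoc tests not run")
    }
  }
  pairs <- utils::combn(names(samples), 2)
  m <- n_tests %||% ncol(pairs)
  rows <- apply(pairs, 2, function(pr) {
    x <- samples[[pr[1]]]; y <- samples[[pr[2]]]
    exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2], U = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p, m)
  out
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, `3 <= n <= 5000`, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (length(unique(values)) == 1) stop("Shapiro-Wilk undefined for constant input")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Groupwise comparison table for a set of features
#'
#' One Kruskal-Wallis test per feature column, Bonferroni-corrected across
#' the features tested (the study's summary-table layout: statistic, df, p).
#' Pairwise Mann-Whitney post-hocs are attached (attribute `"pairwise"`) for
#' features whose corrected omnibus p is below `alpha`.
#'
#' @param features data frame of per-subject rows.
#' @param cols feature column names to test.
#' @param group_col grouping column (default `"group"`).
#' @param alpha significance level applied to the corrected p.
#' @return data frame with `feature`, `statistic`, `df`, `p`, `p_bonf`,
#'   `significant`, plus group medians and IQRs.
#' @export
feature_group_tests <- function(features, cols, group_col = "group", alpha = 0.05) {
  groups <- split(seq_len(nrow(features)), features[[group_col]])
  rows <- lapply(cols, function(cl) {
    samples <- lapply(groups, function(idx) features[[cl]][idx])
    kw <- kruskal_wallis(samples)
    med <- vapply(samples, stats::median, numeric(1))
    iqr <- vapply(samples, stats::IQR, numeric(1))
    row <- data.frame(feature = cl, statistic = kw$statistic, df = kw$df,
                      p = kw$p, stringsAsFactors = FALSE)
    for (g in names(med)) {
      row[[paste0("median_", g)]] <- med[[g]]
      row[[paste0("iqr_", g)]] <- iqr[[g]]
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p, length(cols))
  out$significant <- out$p_bonf < alpha
  pw <- lapply(cols[out$significant], function(cl) {
    samples <- lapply(groups, function(idx) features[[cl]][idx])
    pairwise_mannwhitney(samples)
  })
  names(pw) <- cols[out$significant]
  attr(out, "pairwise") <- pw
  out
}
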