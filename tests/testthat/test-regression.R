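# OLS reporting, information criteria, all-subsets search, collinearity
# diagnostics, stepwise selection, and prediction.

random_design <- function(n, k) {
  matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
}

test_that("an exact linear relation is fit exactly", {
  x <- data.frame(x = c(1, 2, 3, 4, 5))
  fit <- fit_ols(x, 2 * x$x)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse, 0)
  expect_identical(fit$aic, -Inf) # SSE = 0 sentinel preserves rank order
})

test_that("fit_ols matches the normal-equations oracle on random designs", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    k <- sample(1:4, 1)
    if (n <= k + 1) next
    X <- random_design(n, k)
    y <- rnorm(n)
    fit <- fit_ols(as.data.frame(X), y)
    M <- cbind(1, X)
    beta <- solve(t(M) %*% M, t(M) %*% y)
    expect_lt(max(abs(fit$coefficients - drop(beta))), 1e-10)
    res <- y - drop(M %*% beta)
    sse <- sum(res^2)
    expect_equal(fit$rmse, sqrt(sse / n), tolerance = 1e-10)
    expect_equal(fit$r2, 1 - sse / sum((y - mean(y))^2), tolerance = 1e-10)
    se_oracle <- sqrt(diag(solve(t(M) %*% M)) * sse / (n - k - 1))
    expect_equal(unname(fit$se), unname(se_oracle), tolerance = 1e-8)
    beta_std <- drop(beta)[-1] * apply(X, 2, sd) / sd(y)
    expect_equal(unname(fit$beta_std), unname(beta_std), tolerance = 1e-10)
  }
})

test_that("a strong univariate slope is recovered within its standard error", {
  set.seed(23)
  x <- runif(21, 0.3, 0.7) # delta-fraction-like range
  y <- -30 + 10.248 * x + rnorm(21, 0, 0.15)
  fit <- fit_ols(data.frame(RP_delta = x), y)
  expect_lt(abs(fit$coefficients[["RP_delta"]] - 10.248), 3 * fit$se[["RP_delta"]])
})

test_that("fit_ols rejects singular and undersized problems, naming columns", {
  X <- data.frame(a = 1:10, b = (1:10) * 2)
  expect_error(fit_ols(X, rnorm(10)), "singular design.*b")
  expect_error(fit_ols(data.frame(a = 1:2), rnorm(2)), "n > k")
})

test_that("rmse is the population residual standard deviation", {
  expect_equal(rmse(c(1, -1), c(0, 0)), 1.0)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt((9 + 16) / 2))
  expect_error(rmse(1:3, 1:2), "lengths differ")
})

test_that("information criteria penalise parameters and match the closed form", {
  set.seed(31)
  n <- 21
  x1 <- rnorm(n)
  y <- x1 + rnorm(n)
  X <- data.frame(x1 = x1, x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  small <- fit_ols(X[, "x1", drop = FALSE], y)
  # hand formula oracle
  sse <- sum(small$residuals^2)
  expect_equal(small$aic, n * log(sse / n) + 2 * 2, tolerance = 1e-12)
  expect_equal(small$bic, n * log(sse / n) + 2 * log(n), tolerance = 1e-12)

  # same SSE, more parameters: both criteria prefer the smaller model
  ic_small <- c(aic = n * log(sse / n) + 2 * 3, bic = n * log(sse / n) + 3 * log(n))
  ic_big <- c(aic = n * log(sse / n) + 2 * 5, bic = n * log(sse / n) + 5 * log(n))
  expect_true(all(ic_small < ic_big))

  # an extra predictor orthogonalized against the response adds no SSE
  # reduction, so BIC prefers the smaller model at n = 21
  X$x2 <- stats::lm.fit(cbind(1, x1, y), X$x2)$residuals
  big <- fit_ols(X[, c("x1", "x2")], y)
  expect_lt(small$bic, big$bic)
  expect_identical(information_criteria(small), c(aic = small$aic, bic = small$bic))
})

test_that("all-subsets search enumerates every non-empty predictor subset", {
  set.seed(37)
  X <- as.data.frame(random_design(25, 6))
  y <- X$x1 + 0.5 * X$x2 + rnorm(25)
  subsets <- all_subsets(X, y)
  expect_identical(nrow(subsets), 63L) # 2^6 - 1
  expect_identical(nrow(all_subsets(X["x1"], y)), 1L)
  # nested least squares: the full model attains the minimum training RMSE
  full_rmse <- subsets$rmse[subsets$k == 6]
  expect_true(all(full_rmse <= subsets$rmse + 1e-12))
  best3 <- attr(subsets, "best_per_size")
  expect_true(all(table(best3$k) <= 3))
  expect_error(all_subsets(as.data.frame(random_design(25, 21)), rnorm(25)),
               "1 to 20")
})

test_that("R-squared is non-decreasing along nested predictor chains", {
  set.seed(41)
  X <- as.data.frame(random_design(30, 5))
  y <- rnorm(30)
  r2 <- vapply(seq_len(5), function(k) fit_ols(X[seq_len(k)], y)$r2, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("standardized betas are invariant to predictor rescaling", {
  set.seed(43)
  X <- as.data.frame(random_design(20, 2))
  y <- X$x1 - X$x2 + rnorm(20)
  f1 <- fit_ols(X, y)
  X2 <- X; X2$x1 <- X2$x1 * 1000
  f2 <- fit_ols(X2, y)
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-10)
  expect_equal(f1$coefficients[["x1"]], f2$coefficients[["x1"]] * 1000,
               tolerance = 1e-10)
})

test_that("collinearity diagnostics match the auxiliary-regression oracle", {
  X <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  cc <- collinearity(X)
  expect_equal(cc$vif, c(1, 1), tolerance = 1e-10)

  X2 <- data.frame(a = rnorm(10))
  X2$b <- X2$a
  cc2 <- collinearity(X2)
  expect_true(any(is.infinite(cc2$vif)))

  set.seed(47)
  X3 <- data.frame(a = rnorm(50))
  X3$b <- X3$a + rnorm(50, 0, 0.05)
  cc3 <- collinearity(X3)
  r2_aux <- summary(lm(b ~ a, X3))$r.squared
  expect_equal(cc3$vif[cc3$predictor == "b"], 1 / (1 - r2_aux), tolerance = 1e-8)
})

test_that("stepwise keeps a strong predictor and rarely admits pure noise", {
  # With 3 noise candidates each screened at p_enter = 0.05, exact selection
  # of only the strong predictor has analytic probability ~0.95^3 = 0.857
  # (entry of the strong predictor is essentially certain at effect 10 SD);
  # assert the rate above 0.857 - 3 * sqrt(0.857*0.143/200) = 0.78.
  set.seed(53)
  hits <- 0
  for (r in 1:200) {
    X <- as.data.frame(random_design(30, 4))
    names(X) <- c("strong", "n1", "n2", "n3")
    y <- 10 * X$strong + rnorm(30)
    tr <- stepwise(X, y)
    if (identical(tr$selected, "strong")) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.78)
})

test_that("exactly one of a perfectly collinear informative pair enters", {
  set.seed(59)
  x <- rnorm(25)
  X <- data.frame(a = x, b = x)
  y <- 3 * x + rnorm(25, 0, 0.1)
  tr <- stepwise(X, y)
  expect_identical(length(tr$selected), 1L)
})

test_that("stepwise recovers an exact generative model perfectly", {
  set.seed(61)
  X <- as.data.frame(random_design(24, 6))
  names(X) <- CANDIDATES
  truth <- c(RP_theta = -3.962, RP_delta = 3.217, latency = 6.186,
             amplitude = -0.006)
  y <- 2.312 + drop(as.matrix(X[, names(truth)]) %*% truth)
  tr <- stepwise(X, y)
  expect_setequal(tr$selected, names(truth))
  expect_lt(max(abs(tr$final$coefficients[names(truth)] - truth)), 1e-8)
  expect_lt(abs(tr$final$coefficients[["(Intercept)"]] - 2.312), 1e-8)
  # per-step R^2 never decreases
  expect_true(all(diff(tr$steps$r2) >= -1e-12))
  # excluded-variable collinearity stats are reported for the leftovers
  expect_setequal(tr$excluded$predictor, setdiff(CANDIDATES, names(truth)))
})

test_that("predict_volume evaluates the affine model with unit conventions", {
  model <- list(coefficients = c("(Intercept)" = 2.312, RP_theta = -3.962,
                                 RP_delta = 3.217, latency = 6.186,
                                 amplitude = -0.006))
  feats <- data.frame(RP_theta = 0.23, RP_delta = 0.58, latency = 0.27,
                      amplitude = 51.18)
  oracle <- 2.312 - 3.962 * 0.23 + 3.217 * 0.58 + 6.186 * 0.27 - 0.006 * 51.18
  expect_equal(predict_volume(model, feats), oracle, tolerance = 1e-12)

  zero <- data.frame(RP_theta = 0, RP_delta = 0, latency = 0, amplitude = 0)
  expect_equal(predict_volume(model, zero), 2.312)

  a <- feats; b <- feats * 0.5
  ab <- feats + feats * 0.5
  expect_equal(predict_volume(model, a) + predict_volume(model, b) - 2.312,
               predict_volume(model, ab), tolerance = 1e-12)

  expect_error(predict_volume(model, feats[, -1]), "RP_theta")
})

test_that("model serialization round-trips through JSON", {
  set.seed(67)
  X <- as.data.frame(random_design(15, 2))
  y <- X$x1 + rnorm(15)
  fit <- fit_ols(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(predict_volume(back, X), unname(fit$fitted), tolerance = 1e-10)
})

test_that("univariate table reports per-predictor fits with corrected p", {
  set.seed(71)
  X <- as.data.frame(random_design(21, 7))
  y <- 2 * X$x1 + rnorm(21)
  uni <- univariate_regressions(X, y)
  expect_identical(nrow(uni), 7L)
  expect_equal(uni$p_bonf, pmin(1, uni$p * 7))
  f1 <- fit_ols(X["x1"], y)
  expect_equal(uni$B[uni$predictor == "x1"], unname(f1$coefficients["x1"]))
})
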