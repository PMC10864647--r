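test_that("Savitzky-Golay filtering reproduces polynomials and derivatives", {
  wl <- seq(240, 300, 1)
  quad <- 2 + 0.5 * (wl - 250) + 0.01 * (wl - 250)^2
  expect_equal(sgf_preprocess(quad, sgf_config(window = 11, deriv = 0)), quad,
               tolerance = 1e-8)
  d1 <- sgf_preprocess(2 * wl, sgf_config(window = 7, deriv = 1), 1)
  expect_equal(d1, rep(2, length(wl)), tolerance = 1e-8)

  # second derivative, window 19, against a literal local polynomial fit
  set.seed(6)
  row <- as.numeric(stats::filter(rnorm(81), rep(1 / 9, 9), circular = TRUE))
  cfg <- sgf_config(window = 19, deriv = 2)
  out <- sgf_preprocess(row, cfg, 1)
  half <- 9
  oracle <- sapply((half + 1):(81 - half), function(i) {
    idx <- (i - half):(i + half)
    fit <- lm(row[idx] ~ poly(idx - i, 2, raw = TRUE))
    2 * coef(fit)[3]   # second derivative of the local quadratic at 0
  })
  expect_equal(out[(half + 1):(81 - half)], unname(oracle), tolerance = 1e-8)

  expect_error(sgf_config(window = 4), "odd")
  expect_error(sgf_config(window = 3, deriv = 3), "polyorder")
  expect_error(sgf_preprocess(matrix(1:10, 1), sgf_config(window = 31)),
               "exceeds")
})

test_that("NIPALS PLS1 matches the independent reference implementation", {
  set.seed(14)
  for (r in 1:5) {
    X <- matrix(rnorm(30 * 10), 30, dimnames = list(NULL, paste0("w", 1:10)))
    y <- rnorm(30)
    for (A in 1:3) {
      fit <- fit_pls1(X, y, A)
      ref <- mixOmics::pls(X, y, ncomp = A, mode = "regression",
                           scale = FALSE)
      pref <- predict(ref, X)$predict[, , A]
      expect_lt(max(abs(predict_pls1(fit, X) - pref)), 1e-6)
    }
  }
})

test_that("PLS1 recovers single-channel responses and respects the OLS bound", {
  set.seed(15)
  # centered orthonormal design: the first weight vector then points
  # exactly at the generating channel, so one component reproduces the
  # response
  X <- qr.Q(qr(scale(matrix(rnorm(40 * 12), 40), scale = FALSE)))
  y <- 3 * X[, 5]
  fit <- fit_pls1(X, y, 1)
  pred <- predict_pls1(fit, X)
  expect_gt(1 - sum((pred - y)^2) / sum((y - mean(y))^2), 1 - 1e-8)

  X <- matrix(rnorm(40 * 12), 40)
  y2 <- rnorm(40)
  fit_full <- fit_pls1(X, y2, 12)
  sse_pls <- sum((predict_pls1(fit_full, X) - y2)^2)
  sse_ols <- sum(lm.fit(cbind(1, X), y2)$residuals^2)
  expect_lt(sse_pls, sse_ols + 1e-8)

  expect_error(fit_pls1(X, rep(1, 40), 2), "zero-variance")
  expect_error(fit_pls1(X, y2, 40), "A must be")
})

test_that("NIPALS internals satisfy orthogonality and monotone-fit properties", {
  set.seed(16)
  X <- matrix(rnorm(25 * 15), 25)
  y <- rnorm(25)
  fit <- fit_pls1(X, y, 8)
  G <- crossprod(fit$Tt)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_equal(colSums(fit$W^2), rep(1, 8), tolerance = 1e-12)

  sses <- sapply(1:8, function(a) sum((predict_pls1(fit, X, A = a) - y)^2))
  expect_true(all(diff(sses) <= 1e-8))
})

test_that("PLS prediction paths agree (coefficients vs scores, centering)", {
  set.seed(17)
  X <- matrix(rnorm(20 * 9), 20)
  y <- rnorm(20)
  fit <- fit_pls1(X, y, 4)
  # score-space path on the training data
  pred_scores <- as.numeric(fit$Tt %*% fit$q + fit$y_mean)
  expect_equal(predict_pls1(fit, X), pred_scores, tolerance = 1e-10)
  # the centering identity: predicting the mean spectrum gives mean(y)
  expect_equal(predict_pls1(fit, matrix(fit$x_mean, 1)), fit$y_mean,
               tolerance = 1e-10)
  expect_error(predict_pls1(fit, matrix(0, 2, 5)), "mismatch")
})

test_that("PLS grid tuning selects by the scaled CV criterion", {
  sim <- tiny_ds(noise_sd = 0.002)
  ds <- sim$dataset
  # degenerate single-cell grid returns that cell
  t1 <- tune_pls(ds, 1, a_values = 2, deriv_values = 1, window_values = 7)
  expect_equal(nrow(t1$results), 1)
  expect_equal(t1$best$A, 2)
  expect_equal(t1$best$window, 7)

  # row count is the full Cartesian product
  t2 <- tune_pls(ds, "lys", a_values = 1:4, deriv_values = 0:1,
                 window_values = c(5, 9))
  expect_equal(nrow(t2$results), 4 * 2 * 2)
  expect_equal(t2$best$ssecv_scaled, min(t2$results$ssecv_scaled))

  # a noise-free bilinear problem is fully recoverable
  sim0 <- tiny_ds(noise_sd = 0)
  t3 <- tune_pls(sim0$dataset, "lys", a_values = 1:4, deriv_values = 0:1,
                 window_values = c(5, 9))
  expect_gt(t3$best$r2cv, 0.99)
})
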