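test_that("Grad-CAM maps have the right support, sign and gradients", {
  arch <- cnn_architecture(1, 3, 5, fc_units = 6)
  m <- build_cnn(arch, 21, 2, seed = 3)
  m$params$out_b <- m$params$out_b + 0.5   # keep outputs off the ReLU kink
  x <- rnorm(21)
  gc <- gradcam_map(m, x, 1)
  expect_equal(length(gc$values), 21)
  expect_true(all(gc$values >= 0))

  # alpha weights against finite differences through the conv bias: adding
  # eps to filter k's bias raises every feature-map position by eps (linear
  # conv activation), so d(out)/d(bias_k) = L_c * alpha_k.
  Lc <- gc$metadata$feature_length
  fd <- sapply(1:3, function(k) {
    m2 <- m; m2$params$conv1_b[k] <- m2$params$conv1_b[k] + 1e-5
    m3 <- m; m3$params$conv1_b[k] <- m3$params$conv1_b[k] - 1e-5
    (predict_cnn(m2, x)[1, 1] - predict_cnn(m3, x)[1, 1]) / 2e-5 / Lc
  })
  expect_lt(max(abs(gc$metadata$alpha - fd)), 1e-4)

  # zeroed output weights kill every gradient: the map is identically zero
  mz <- m
  mz$params$out_W[] <- 0
  expect_equal(max(abs(gradcam_map(mz, x, 1)$values)), 0)

  expect_error(gradcam_map(m, x, 5), "out of range")
})

test_that("permutation Shapley values are exact on linear models and additive", {
  beta <- c(2, 0, 1)
  f <- function(X) X %*% beta
  sh <- permutation_shap(f, background = matrix(0, 1, 3),
                         explain = matrix(c(1, 1, 2), 1),
                         n_permutations = 4, seed = 1)
  expect_equal(sh$per_sample[1, ], c(2, 0, 2), tolerance = 1e-12)

  # constant model attributes nothing
  fc <- function(X) rep(3.3, nrow(X))
  shc <- permutation_shap(fc, matrix(rnorm(12), 4, 3), matrix(rnorm(3), 1),
                          n_permutations = 3, seed = 2)
  expect_equal(max(abs(shc$per_sample)), 0)

  # additivity with a multi-row background and a nonlinear model
  set.seed(3)
  g <- function(X) sin(X[, 1]) + X[, 2] * X[, 3] + exp(0.3 * X[, 4])
  bg <- matrix(rnorm(20), 5, 4)
  ex <- matrix(rnorm(8), 2, 4)
  sh2 <- permutation_shap(g, bg, ex, n_permutations = 6, seed = 4)
  expect_equal(rowSums(sh2$per_sample),
               sh2$metadata$fx - sh2$metadata$base_values, tolerance = 1e-8)

  # symmetry: duplicated features get equal attribution for a linear model
  fdup <- function(X) X[, 1] + X[, 2]
  shd <- permutation_shap(fdup, matrix(0, 1, 2), matrix(c(1.5, 1.5), 1),
                          n_permutations = 5, seed = 5)
  expect_equal(shd$per_sample[1, 1], shd$per_sample[1, 2], tolerance = 1e-12)

  expect_error(permutation_shap(f, matrix(0, 0, 3), matrix(0, 1, 3)),
               "empty")
})

test_that("the permutation estimator converges to exhaustive Shapley values", {
  set.seed(11)
  W <- matrix(rnorm(10), 5, 2)
  f <- function(X) tanh(X %*% W[, 1]) + 0.5 * (X %*% W[, 2])^2
  x <- rnorm(5)
  bg <- rnorm(5)
  exact <- exact_shapley(f, x, bg)
  est <- permutation_shap(f, matrix(bg, 1), matrix(x, 1),
                          n_permutations = 1000, seed = 12)
  rng <- diff(range(exact))
  expect_lt(max(abs(est$per_sample[1, ] - exact)), 0.05 * rng)
})

test_that("VIP scores obey the closed form and its normalization", {
  set.seed(13)
  # A = 1 with equal-magnitude weights: construct y so that the centered
  # cross-covariance X'y is the all-ones vector
  X <- scale(matrix(rnorm(30 * 8), 30), center = TRUE, scale = FALSE)
  y <- as.numeric(X %*% solve(crossprod(X), rep(1, 8)))
  fit1 <- fit_pls1(X, y, 1)
  v1 <- vip_scores(fit1)
  expect_equal(v1$values, rep(1, 8), tolerance = 1e-8)

  # normalization identity and brute-force formula agreement
  X2 <- matrix(rnorm(40 * 12), 40)
  y2 <- rnorm(40)
  fit <- fit_pls1(X2, y2, 5)
  v <- vip_scores(fit)
  expect_equal(mean(v$values^2), 1, tolerance = 1e-8)
  N <- 12
  ss <- sapply(1:5, function(a) fit$q[a]^2 * sum(fit$Tt[, a]^2))
  oracle <- sapply(1:N, function(j) {
    sqrt(N * sum(ss * (fit$W[j, ] / sqrt(colSums(fit$W^2)))^2) / sum(ss))
  })
  expect_equal(v$values, oracle, tolerance = 1e-10)
  expect_true(all(v$values >= 0))
})

test_that("PLS coefficients scale linearly and reproduce predictions", {
  set.seed(18)
  wl <- seq(240, 270, 1)
  X <- matrix(rnorm(25 * 31), 25)
  y <- 2 * X[, 10] + rnorm(25, 0, 0.01)
  fit <- fit_pls1(X, y, 3)
  co <- pls_coefficients(fit, wl)
  # localization on the generating channel (no smoothing configured)
  expect_equal(which.max(abs(co$values)), 10)
  # doubling the response doubles the coefficients
  fit2 <- fit_pls1(X, 2 * y, 3)
  expect_equal(pls_coefficients(fit2)$values, 2 * co$values,
               tolerance = 1e-8)
  # two-path equivalence: direct dot product equals predict_pls1
  direct <- as.numeric(sweep(X, 2, fit$x_mean) %*% co$values + fit$y_mean)
  expect_equal(direct, predict_pls1(fit, X), tolerance = 1e-10)

  # with an SGF chain the stored metadata reproduces predictions too
  fit_s <- fit_pls1(X, y, 3, sgf = sgf_config(window = 5), wavelength_step = 1)
  co_s <- pls_coefficients(fit_s)
  Z <- sgf_preprocess(X, co_s$metadata$sgf, 1)
  direct_s <- as.numeric(sweep(Z, 2, co_s$metadata$x_mean) %*% co_s$values +
                           co_s$metadata$y_mean)
  expect_equal(direct_s, predict_pls1(fit_s, X), tolerance = 1e-10)
})
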