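test_that("concentration samplers fit and draw per the declared modes", {
  # degenerate uniform range -> constant draws
  s <- fit_sampler(matrix(c(2, 2, 2), 3), "uniform")
  expect_equal(unname(sample_concentrations(s, 5, seed = 1)[, 1]),
               rep(2, 5))

  # normal mode stores sample mean and SD
  s <- fit_sampler(matrix(c(0, 2, 4), 3), "normal")
  expect_equal(s$components[[1]]$mean, 2)
  expect_equal(s$components[[1]]$sd, sd(c(0, 2, 4)))

  # KDE draws recover the fitted location
  set.seed(5)
  s <- fit_sampler(matrix(rnorm(2000, 5, 1), 2000), "kde")
  draws <- sample_concentrations(s, 1e4, seed = 2)
  expect_lt(abs(mean(draws) - 5), 0.05)

  # zero-variance column degenerates to a point mass with a warning
  expect_warning(sz <- fit_sampler(matrix(3, 4, 1), "kde"), "zero-variance")
  expect_equal(unname(sample_concentrations(sz, 3)[, 1]), rep(3, 3))
})

test_that("sampled concentrations are non-negative and reproducible", {
  set.seed(8)
  Y <- matrix(c(rexp(20, 5), rnorm(20, 100, 1)), 20)
  s <- fit_sampler(Y, "kde")
  expect_equal(nrow(sample_concentrations(s, 0)), 0)
  d1 <- sample_concentrations(s, 50, seed = 3)
  d2 <- sample_concentrations(s, 50, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
  # far from zero: no clamping events in 1e4 draws
  s2 <- fit_sampler(Y[, 2, drop = FALSE], "kde")
  expect_equal(sum(sample_concentrations(s2, 1e4, seed = 4) == 0), 0)
})

test_that("local subset selection matches hand cases and a full-sort oracle", {
  expect_equal(select_local_subset(matrix(c(0, 1, 2), 3), 0.9, 1), 2L)
  # l = 1 vs l = 2 pick different neighbors
  Y <- rbind(A = c(3, 0), B = c(2, 2))
  expect_equal(select_local_subset(Y, c(0, 0), 1, norm_order = 1), 1L)
  expect_equal(select_local_subset(Y, c(0, 0), 1, norm_order = 2), 2L)

  expect_error(select_local_subset(Y, c(0, 0), 3), "exceeds")

  set.seed(21)
  for (r in 1:300) {
    M <- sample(3:25, 1)
    P <- sample(1:4, 1)
    Ym <- matrix(round(runif(M * P), 2), M)   # rounding forces ties
    ystar <- runif(P)
    n <- sample.int(M, 1)
    l <- sample(c(1, 2), 1)
    d <- apply(Ym, 1, function(row) {
      if (l == 1) sum(abs(row - ystar)) else sqrt(sum((row - ystar)^2))
    })
    oracle <- order(d, seq_len(M))[seq_len(n)]
    expect_identical(select_local_subset(Ym, ystar, n, l), oracle)
  }
})

test_that("pure-component estimation honors both solvers", {
  # identity design returns the observed spectra as profiles
  s1 <- c(1, 2, 3)
  s2 <- c(4, 5, 6)
  est <- estimate_pure_components(rbind(s1, s2), diag(2), "ols")
  expect_equal(est$S, cbind(s1, s2), tolerance = 1e-12, ignore_attr = TRUE)

  # single negative sample: OLS keeps the sign, NNLS clips it
  expect_equal(estimate_pure_components(matrix(-0.5), matrix(1), "ols")$S[1, 1],
               -0.5)
  expect_equal(estimate_pure_components(matrix(-0.5), matrix(1), "nnls")$S[1, 1],
               0)

  # noise-free recovery by both solvers
  set.seed(3)
  S_true <- matrix(runif(8 * 5, 0.1, 2), 8, 5)
  Y <- matrix(runif(20 * 5, 0.2, 3), 20, 5)
  X <- Y %*% t(S_true)
  for (sv in c("ols", "nnls")) {
    est <- estimate_pure_components(X, Y, sv)
    expect_lt(max(abs(est$S - S_true)), 1e-8)
  }

  expect_error(estimate_pure_components(matrix(1, 2, 3), matrix(0, 2, 2)),
               "singular")
  expect_warning(
    estimate_pure_components(matrix(1:4, 2), matrix(c(1, 2, 2, 4), 2), "ols"),
    "rank-deficient")
})

test_that("batched NNLS agrees with the Lawson-Hanson oracle", {
  set.seed(9)
  worst_obj <- 0
  for (r in 1:200) {
    n <- sample(3:12, 1)
    P <- sample(1:5, 1)
    A <- matrix(rnorm(n * P), n)
    b <- rnorm(n)
    mine <- nnls_multi(A, b)[, 1]
    expect_true(all(mine >= 0))
    ref <- pracma::lsqnonneg(A, b)$x
    worst_obj <- max(worst_obj, sum((A %*% mine - b)^2) -
                       sum((A %*% ref - b)^2))
    ols <- qr.solve(A, b)
    if (all(ols >= 0)) expect_lt(max(abs(mine - ols)), 1e-8)
  }
  expect_lt(worst_obj, 1e-8)
})

test_that("spectrum synthesis is the bilinear mixing map", {
  S <- matrix(rnorm(12), 4, 3)
  expect_equal(synthesize_spectrum(S, c(0, 1, 0)), S[, 2])
  expect_equal(synthesize_spectrum(S, c(0, 0, 0)), rep(0, 4))
  y1 <- runif(3); y2 <- runif(3)
  expect_equal(synthesize_spectrum(S, 2 * y1 + 3 * y2),
               2 * synthesize_spectrum(S, y1) + 3 * synthesize_spectrum(S, y2),
               tolerance = 1e-12)
  expect_error(synthesize_spectrum(S, c(1, 2)), "does not match")
})

test_that("perturbation shifts then adds noise as declared", {
  wl <- seq(240, 260, 1)
  x <- sin(wl / 3)
  expect_equal(perturb_spectrum(x, wl, 0, 0), x)
  # forced +1 grid-step shift moves the spectrum by one index, edge held
  sh <- perturb_spectrum(x, wl, 0, 0, delta = 1)
  expect_equal(sh[2:21], x[1:20], tolerance = 1e-12)
  expect_equal(sh[1], x[1])
  # Monte-Carlo noise SD within 5%
  s <- 0.02
  set.seed(31)
  reps <- t(replicate(400, perturb_spectrum(x, wl, s, 0)))
  sds <- apply(reps, 2, sd)
  expect_lt(abs(mean(sds) - s) / s, 0.05)
  expect_error(perturb_spectrum(x, wl, -1, 0), ">= 0")
})

test_that("augmentation reproduces the bilinear ground truth when unperturbed", {
  sim <- tiny_ds(noise_sd = 0)
  ds <- sim$dataset
  cfg <- lsa_config(n_lsa = 9, sigma_noise = 0, sigma_shift = 0,
                    n_gen = 40, seed = 17)
  aug <- augment_dataset(ds, cfg)
  expect_equal(nrow(aug$X_star), 40)
  expect_true(all(is.finite(aug$X_star)))
  expect_lt(max(abs(aug$X_star - aug$Y_star %*% t(sim$S_true$S))), 1e-6)

  aug2 <- augment_dataset(ds, cfg)
  expect_identical(aug$X_star, aug2$X_star)
  expect_identical(aug$Y_star, aug2$Y_star)

  expect_error(augment_dataset(ds, lsa_config(n_lsa = 1000, n_gen = 1)),
               "exceeds")
})

test_that("reconstruction CV vanishes on noise-free data and tracks noise", {
  sim <- tiny_ds(noise_sd = 0)
  rc <- reconstruction_cv(sim$dataset, lsa_config(n_lsa = 9))
  expect_lt(rc$rmsecv, 1e-6)
  expect_equal(length(rc$per_group), 3)

  # noise floor: rmsecv within a factor 2 of the injected SD
  s <- 0.02
  simn <- make_dataset(ds1_like_spec(noise_sd = s, n_experiments = 3,
                                     n_fractions = 60, seed = 19))
  rcn <- reconstruction_cv(simn$dataset, lsa_config(n_lsa = 15))
  expect_gt(rcn$rmsecv, s / 2)
  expect_lt(rcn$rmsecv, s * 2)

  one_group <- sim$dataset
  one_group$groups <- rep("only", nrow(one_group$X))
  expect_error(reconstruction_cv(one_group, lsa_config()), "at least 2 groups")
  expect_error(reconstruction_cv(sim$dataset, lsa_config(n_lsa = 30)),
               "rotation")
})

test_that("reconstruction error does not decrease with injected noise", {
  s <- 0.01
  for (seed in 1:3) {
    r <- sapply(c(0, s, 10 * s), function(ns) {
      sim <- make_dataset(ds1_like_spec(noise_sd = ns, seed = 40 + seed,
                                        n_experiments = 3, n_fractions = 15))
      reconstruction_cv(sim$dataset, lsa_config(n_lsa = 9))$rmsecv
    })
    expect_true(all(diff(r) > 0))
  }
})

test_that("LSA grid tuning evaluates the full product and breaks ties as stated", {
  sim <- tiny_ds(noise_sd = 0)
  tl <- tune_lsa(sim$dataset, list(n_lsa = c(5L, 20L)))
  expect_equal(nrow(tl$results), 2)
  expect_equal(tl$best_config$n_lsa,
               tl$results$n_lsa[which.min(tl$results$rmsecv)])
  # on noise-free data every full-rank configuration reconstructs exactly
  expect_true(all(tl$results$rmsecv < 1e-6))

  tl2 <- tune_lsa(sim$dataset, list(n_lsa = c(6L, 9L), norm_order = c(1, 2),
                                    solver = "nnls"))
  expect_equal(nrow(tl2$results), 4)
  expect_true(all(tl2$results$rmsecv >= min(tl2$results$rmsecv)))

  expect_error(tune_lsa(sim$dataset, list()), "non-empty")
  expect_error(tune_lsa(sim$dataset, list(bogus = 1)), "unknown grid")
})
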