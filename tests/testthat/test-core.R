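test_that("dataset construction enforces its invariants", {
  X <- matrix(1:12, 3, 4)
  Y <- matrix(1:3, 3, 1)
  wl <- c(240, 241, 242, 243)
  ds <- spectral_dataset(X, Y, wl, "lys", groups = c("a", "a", "b"))
  expect_s3_class(ds, "spectral_dataset")
  expect_equal(dim(ds), c(3, 4, 1))

  expect_error(spectral_dataset(X, Y[1:2, , drop = FALSE], wl, "lys"),
               "row counts")
  expect_error(spectral_dataset(X, Y, c(300, 240, 270, 280), "lys"),
               "strictly increasing")
  expect_error(spectral_dataset(X[, 1, drop = FALSE], Y, 240), "2 wavelengths")
  expect_error(spectral_dataset(X, Y, wl, c("a", "b")), "length 1")
  expect_error(spectral_dataset(X, Y, wl, "lys", groups = "a"), "length 3")

  sub <- subset_samples(ds, ds$groups == "a")
  expect_equal(nrow(sub$X), 2)
  expect_equal(sub$sample_ids, c("s1", "s2"))
})

test_that("CSV round trip is lossless, preserves unicode names, aligns by ID", {
  sim <- tiny_ds(noise_sd = 0.002)
  ds <- sim$dataset
  ds$component_names <- c("α-ribA", "cyt C", "lyßzyme")
  colnames(ds$Y) <- ds$component_names
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  back <- read_dataset(paths["spectra"], paths["concentrations"])
  expect_equal(back$X, ds$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$Y, ds$Y, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$component_names, ds$component_names)
  expect_identical(back$groups, ds$groups)
  expect_equal(back$wavelengths, ds$wavelengths)

  # alignment by sample ID, not row order
  co <- utils::read.csv(paths["concentrations"], check.names = FALSE)
  co <- co[rev(seq_len(nrow(co))), ]
  shuffled <- file.path(dir, "shuffled.csv")
  utils::write.csv(co, shuffled, row.names = FALSE, fileEncoding = "UTF-8")
  back2 <- read_dataset(paths["spectra"], shuffled)
  expect_equal(back2$Y, ds$Y, tolerance = 1e-12, ignore_attr = TRUE)

  # malformed inputs
  co$sample_id[1] <- "nonexistent"
  utils::write.csv(co, shuffled, row.names = FALSE)
  expect_error(read_dataset(paths["spectra"], shuffled), "do not match")
  sp <- utils::read.csv(paths["spectra"], check.names = FALSE)
  names(sp)[3:4] <- c("300", "240")
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(sp, bad, row.names = FALSE)
  expect_error(read_dataset(bad, paths["concentrations"]),
               "strictly increasing")
})

test_that("metrics match hand arithmetic and a naive loop oracle", {
  # constant y_true: RMSE/NRMSE defined, R2 flagged undefined
  m <- suppressWarnings(compute_metrics(c(1, 1), c(2, 2)))
  expect_equal(unname(m$rmse), 1)
  expect_equal(unname(m$nrmse), 1)
  expect_true(is.na(m$r2))

  m0 <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(m0$rmse), 0)
  expect_equal(unname(m0$r2), 1)

  set.seed(42)
  yt <- matrix(rexp(150), 50, 3)
  yp <- yt + matrix(rnorm(150, 0, 0.2), 50, 3)
  m <- compute_metrics(yt, yp)
  for (p in 1:3) {   # naive per-component loop oracle
    rmse <- sqrt(sum((yp[, p] - yt[, p])^2) / 50)
    expect_equal(unname(m$rmse[p]), rmse, tolerance = 1e-12)
    expect_equal(unname(m$nrmse[p]), rmse / mean(yt[, p]), tolerance = 1e-12)
    expect_equal(unname(m$r2[p]),
                 1 - sum((yp[, p] - yt[, p])^2) / sum((yt[, p] - mean(yt[, p]))^2),
                 tolerance = 1e-12)
  }

  # permutation invariance over samples
  perm <- sample(50)
  m2 <- compute_metrics(yt[perm, ], yp[perm, ])
  expect_equal(m2$rmse, m$rmse, tolerance = 1e-12)
  expect_equal(m2$r2, m$r2, tolerance = 1e-12)

  # NRMSE is invariant under a uniform positive rescaling
  m3 <- compute_metrics(3.7 * yt, 3.7 * yp)
  expect_equal(m3$nrmse, m$nrmse, tolerance = 1e-12)

  warns <- capture_warnings(mz <- compute_metrics(c(0, 0), c(0.1, -0.1)))
  expect_match(warns, "non-positive", all = FALSE)
  expect_match(warns, "zero-variance", all = FALSE)
  expect_true(is.na(mz$nrmse))
  expect_warning(mv <- compute_metrics(c(1, 1), c(1.5, 0.5)), "zero-variance")
  expect_true(is.na(mv$r2))
})

test_that("scaled CV criterion follows its degrees-of-freedom formula", {
  expect_equal(sse_cv_scaled(c(1, 1, 1, 1), 2), 4)
  expect_equal(sse_cv_scaled(rep(0, 10), 3), 0)
  expect_error(sse_cv_scaled(c(1, 1, 1), 2), "degrees of freedom")
})
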