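test_that("CNN builder validates widths and reports exact parameter counts", {
  m <- build_cnn(cnn_architecture(1, 1, 3, fc_units = 5), 61, 3, seed = 1)
  out <- predict_cnn(m, matrix(rnorm(5 * 61), 5))
  expect_equal(dim(out), c(5, 3))
  expect_true(all(out >= 0))
  # conv (3*1+1)*1 = 4; flatten 29; fc (29+1)*5 = 150; out (5+1)*3 = 18
  expect_equal(m$n_params, 4 + 150 + 18)

  # three layers with per-layer halving of the feature length
  m3 <- build_cnn(cnn_architecture(3, c(2, 10, 8), c(7, 5, 11),
                                   fc_units = 9), 61, 2, seed = 1)
  lens <- sapply(m3$layers, function(l) if (!is.null(l$l_out)) l$l_out else NA)
  # 61 -> conv7 55 -> pool 27 -> conv5 23 -> pool 11 -> conv11 1
  expect_equal(lens[!is.na(lens)], c(55, 27, 23, 11, 1))
  # conv1 (7*1+1)*2=16; conv2 (5*2+1)*10=110; conv3 (11*10+1)*8=888;
  # fc (8+1)*9=81; out (9+1)*2=20
  expect_equal(m3$n_params, 16 + 110 + 888 + 81 + 20)

  # width 5 on a length-20 input, 2 layers:
  # 20 -> conv5 16 -> pool 8 -> conv5 4 -> pool 2; fc in = 2*4
  m2 <- build_cnn(cnn_architecture(2, c(3, 4), c(5, 5), fc_units = 6), 20, 1,
                  seed = 2)
  expect_equal(m2$n_params, (5 * 1 + 1) * 3 + (5 * 3 + 1) * 4 +
                 (8 + 1) * 6 + (6 + 1) * 1)

  expect_error(build_cnn(cnn_architecture(1, 1, 63), 61, 3), "exceeds")
  expect_error(cnn_architecture(1, 1, 4), "odd")
  expect_error(cnn_architecture(4), "1, 2 or 3")
})

test_that("early stopping follows the patience rule and restores the best epoch", {
  tr <- early_stopping_trace(c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9), patience = 4)
  expect_equal(tr$stop_epoch, 6)
  expect_equal(tr$best_epoch, 2)
  tr2 <- early_stopping_trace(c(5, 4, 3, 2, 1), patience = 4)
  expect_equal(tr2$stop_epoch, 5)
  expect_equal(tr2$best_epoch, 5)
  expect_error(training_config(patience = 100, max_epochs = 100),
               "smaller than")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(2)
  arch <- cnn_architecture(2, c(2, 3), c(5, 3), fc_units = 6,
                           conv_activation = "tanh", l2_factor = 0)
  m <- build_cnn(arch, 20, 2, seed = 9)
  X <- matrix(rnorm(4 * 20), 4)
  Y <- matrix(abs(rnorm(8)), 4)
  fw <- lsaugment:::.cnn_forward(m, X)
  bw <- lsaugment:::.cnn_backward(m, fw$caches,
                                  2 * (fw$pred - Y) / length(Y))
  loss_at <- function(mm) mean((lsaugment:::.cnn_forward(mm, X)$pred - Y)^2)
  for (nm in names(m$params)) {
    g <- bw$grads[[nm]]
    for (j in sample(length(g), min(4, length(g)))) {
      m2 <- m; m2$params[[nm]][j] <- m2$params[[nm]][j] + 1e-6
      m3 <- m; m3$params[[nm]][j] <- m3$params[[nm]][j] - 1e-6
      fd <- (loss_at(m2) - loss_at(m3)) / 2e-6
      expect_lt(abs(fd - g[j]), 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("training is reproducible under seeds and actually learns", {
  set.seed(33)
  N <- 21
  S <- matrix(runif(N * 2, 0.2, 1), N)
  Yc <- matrix(runif(400 * 2, 0, 2), 400)
  Xc <- Yc %*% t(S)
  Yv <- matrix(runif(60 * 2, 0, 2), 60)
  Xv <- Yv %*% t(S)
  arch <- cnn_architecture(1, 3, 5, fc_units = 8)
  cfg <- training_config(max_epochs = 30, patience = 5, seed = 5,
                         batch_size = 50)
  m <- build_cnn(arch, N, 2, seed = 4)
  t1 <- train_cnn(m, Xc, Yc, Xv, Yv, cfg)
  t2 <- train_cnn(build_cnn(arch, N, 2, seed = 4), Xc, Yc, Xv, Yv, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$params, t2$model$params)
  # the loss must drop substantially on this noise-free linear problem
  expect_lt(min(t1$history$val_loss), 0.3 * t1$history$val_loss[1])
  expect_equal(t1$best_epoch, which.min(t1$history$val_loss))
  # weights of the best epoch are restored
  expect_equal(mean((predict_cnn(t1$model, Xv) - Yv)^2),
               min(t1$history$val_loss), tolerance = 1e-12)
})

test_that("dropout and L2 options keep training finite", {
  set.seed(44)
  X <- matrix(runif(200 * 15), 200)
  Y <- matrix(X[, 3] + 0.5, 200, 1)
  arch <- cnn_architecture(1, 2, 3, fc_units = 6, dropout_rate = 0.2,
                           l2_factor = 1e-4)
  m <- build_cnn(arch, 15, 1, seed = 1)
  tr <- train_cnn(m, X, Y, X[1:40, ], Y[1:40, , drop = FALSE],
                  training_config(max_epochs = 8, patience = 3, seed = 2))
  expect_true(all(is.finite(tr$history$train_loss)))
})

test_that("grouped CV pools predictions and honors injected predictors", {
  sim <- tiny_ds(noise_sd = 0)
  ds <- sim$dataset
  # a perfect oracle reaches the maximum objective P
  oracle <- function(ds_train, X_held) {
    S <- estimate_pure_components(ds_train$X, ds_train$Y, "ols")
    t(apply(X_held, 1, function(x) qr.solve(S$S, x)))
  }
  cv <- cross_validate_cnn(ds, cnn_architecture(), lsa_config(),
                           predictor = oracle)
  expect_equal(cv$objective, ncol(ds$Y), tolerance = 1e-6)
  expect_equal(length(cv$rotations), 3)

  # predicting the training mean cannot beat the held-out mean
  mean_pred <- function(ds_train, X_held) {
    matrix(colMeans(ds_train$Y), nrow(X_held), ncol(ds_train$Y), byrow = TRUE)
  }
  cv0 <- cross_validate_cnn(ds, cnn_architecture(), lsa_config(),
                            predictor = mean_pred)
  expect_true(all(cv0$metrics$r2 <= 0 + 1e-12))

  one <- ds
  one$groups <- rep("g", nrow(one$X))
  expect_error(cross_validate_cnn(one, cnn_architecture(), lsa_config()),
               "at least 2 groups")
})

test_that("unaugmented training splits reproducibly and reports the best epoch", {
  sim <- tiny_ds(noise_sd = 0.002)
  ds <- sim$dataset
  r1 <- train_unaugmented(ds, cnn_architecture(1, 2, 5, fc_units = 6),
                          seed = 9, max_epochs = 6)
  r2 <- train_unaugmented(ds, cnn_architecture(1, 2, 5, fc_units = 6),
                          seed = 9, max_epochs = 6)
  expect_identical(r1$cal_idx, r2$cal_idx)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 6)   # early stopping disabled
  expect_equal(r1$best_epoch, which.min(r1$history$val_loss))
  expect_equal(length(r1$cal_idx), round(0.8 * nrow(ds$X)))

  small <- subset_samples(ds, 1:5)
  expect_error(train_unaugmented(small, cnn_architecture(), seed = 1),
               "at least 10")
})
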