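# Adam optimizer state and update.
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Early-stopping bookkeeping over a validation-loss sequence
#'
#' Pure form of the stopping rule used during training: training stops
#' after the first epoch at which the validation loss has failed to improve
#' (strictly) for `patience` consecutive epochs, and the weights of the
#' best epoch are restored.
#'
#' @param val_losses per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return List with `stop_epoch` (last epoch run; `length(val_losses)` if
#'   the rule never fires) and `best_epoch` (argmin of the losses seen up
#'   to the stop).
#' @export
#' @examples
#' early_stopping_trace(c(1, 0.9, 0.9, 0.9, 0.9, 0.9), patience = 4)
early_stopping_trace <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

# Shared minibatch training loop. Uses the current RNG stream (callers
# seed). Monitors mean MSE on (X_val, Y_val); with `early_stop = FALSE`
# runs all epochs and still restores the best-validation epoch.
.cnn_train_loop <- function(model, X_cal, Y_cal, X_val, Y_val, cfg,
                            early_stop = TRUE) {
  l2 <- model$arch$l2_factor
  state <- .adam_init(model$params)
  n <- nrow(X_cal)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_params <- model$params
  best_val <- Inf
  wait <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      Xb <- X_cal[idx, , drop = FALSE]
      Yb <- Y_cal[idx, , drop = FALSE]
      fw <- .cnn_forward(model, Xb, train = TRUE)
      err <- fw$pred - Yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      d_pred <- 2 * err / length(err)
      bw <- .cnn_backward(model, fw$caches, d_pred)
      grads <- bw$grads
      if (l2 > 0) {
        for (nm in names(grads)) {
          grads[[nm]] <- grads[[nm]] + 2 * l2 * model$params[[nm]]
        }
      }
      upd <- .adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    val_pred <- .cnn_forward(model, X_val, train = FALSE)$pred
    val_loss <- mean((val_pred - Y_val)^2)
    if (!is.finite(val_loss)) {
      stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- model$params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (early_stop && wait >= cfg$patience) break
    }
  }
  model$params <- best_params
  best_epoch <- which.min(history$val_loss)
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_loss = best_val)
}

#' Train a CNN on generated spectra with experimental validation
#'
#' Calibrates the model weights on the generated (in-silico) data by
#' minimizing the mean MSE over all responses with Adam; the experimental
#' training data serve only to evaluate the early-stopping criterion.
#' Training stops when the validation loss has not improved for
#' `cfg$patience` consecutive epochs (or at `cfg$max_epochs`), and the
#' weights of the best validation epoch are restored.
#'
#' @param model a [build_cnn()] model.
#' @param X_cal,Y_cal calibration data (generated spectra and sampled
#'   concentrations).
#' @param X_val,Y_val validation data (experimental training spectra and
#'   measured concentrations).
#' @param cfg a [training_config()].
#' @return List with `model` (trained), `history` (per-epoch losses),
#'   `best_epoch`.
#' @export
train_cnn <- function(model, X_cal, Y_cal, X_val, Y_val,
                      cfg = training_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "training_config"))
  X_cal <- as.matrix(X_cal)
  Y_cal <- as.matrix(Y_cal)
  X_val <- as.matrix(X_val)
  Y_val <- as.matrix(Y_val)
  if (nrow(X_cal) != nrow(Y_cal) || nrow(X_val) != nrow(Y_val)) {
    stop("spectra/concentration row counts differ", call. = FALSE)
  }
  if (ncol(X_cal) != model$n_wavelengths ||
      ncol(X_val) != model$n_wavelengths ||
      ncol(Y_cal) != model$n_components ||
      ncol(Y_val) != model$n_components) {
    stop("data dimensions do not match the model", call. = FALSE)
  }
  .with_seed(cfg$seed,
             .cnn_train_loop(model, X_cal, Y_cal, X_val, Y_val, cfg,
                             early_stop = TRUE))
}

#' Leave-one-group-out cross-validation of the augmented CNN workflow
#'
#' For every rotation, the held-out experiment is removed, in-silico data
#' are regenerated from the retained groups only, a fresh model is trained
#' on them (validating against the retained experimental data), and the
#' held-out group is predicted. Predictions are pooled over rotations
#' before computing per-component metrics.
#'
#' @param ds a [spectral_dataset()] with at least 2 groups.
#' @param arch a [cnn_architecture()].
#' @param lsa_cfg an [lsa_config()] used to regenerate data per rotation.
#' @param train_cfg a [training_config()]; its `seed` drives all
#'   rotation-level randomness.
#' @param predictor optional function `(ds_train, X_heldout) ->
#'   predictions` replacing augmentation+training (used for diagnostics and
#'   null-model baselines).
#' @return List with `metrics` (a [compute_metrics()] result on pooled
#'   predictions), `objective` (sum of per-component R2), `predictions`
#'   (M x P, original order), `rotations` (per-rotation bookkeeping).
#' @export
cross_validate_cnn <- function(ds, arch, lsa_cfg,
                               train_cfg = training_config(),
                               predictor = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"))
  groups <- unique(ds$groups)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  P <- ncol(ds$Y)
  preds <- matrix(NA_real_, nrow(ds$X), P)
  rotations <- list()
  for (r in seq_along(groups)) {
    g <- groups[r]
    held <- ds$groups == g
    ds_r <- subset_samples(ds, !held)
    res <- tryCatch({
      if (!is.null(predictor)) {
        p_held <- predictor(ds_r, ds$X[held, , drop = FALSE])
        list(pred = as.matrix(p_held), epochs = NA_integer_)
      } else {
        seed_r <- .child_seed(train_cfg$seed, r)
        lsa_r <- lsa_cfg
        lsa_r$seed <- .child_seed(seed_r, 1L)
        aug <- augment_dataset(ds_r, lsa_r)
        model <- build_cnn(arch, ncol(ds$X), P, seed = .child_seed(seed_r, 2L))
        cfg_r <- train_cfg
        cfg_r$seed <- .child_seed(seed_r, 3L)
        tr <- train_cnn(model, aug$X_star, aug$Y_star, ds_r$X, ds_r$Y, cfg_r)
        list(pred = predict_cnn(tr$model, ds$X[held, , drop = FALSE]),
             epochs = nrow(tr$history))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop("rotation '", g, "': ", conditionMessage(res), call. = FALSE)
    }
    preds[held, ] <- res$pred
    rotations[[g]] <- list(group = g, n_held = sum(held),
                           epochs = res$epochs)
  }
  metrics <- compute_metrics(ds$Y, preds, ds$component_names)
  list(metrics = metrics, objective = sum(metrics$r2), predictions = preds,
       rotations = rotations)
}

#' Train a CNN on experimental data without augmentation
#'
#' Baseline protocol: the experimental data are split randomly into 80/20
#' calibration/validation subsets, the model is trained for a fixed number
#' of epochs with early stopping disabled, and the weights of the epoch
#' with the lowest validation loss are returned.
#'
#' @param ds a [spectral_dataset()] with at least 10 samples.
#' @param arch a [cnn_architecture()].
#' @param seed integer seed (split, initialization, shuffling).
#' @param max_epochs fixed epoch count, default 300.
#' @param learning_rate,batch_size optimizer settings.
#' @return List with `model`, `history`, `best_epoch`, `cal_idx` (indices
#'   of the calibration subset).
#' @export
train_unaugmented <- function(ds, arch, seed = NULL, max_epochs = 300L,
                              learning_rate = 1e-3, batch_size = 100L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  M <- nrow(ds$X)
  if (M < 10L) stop("need at least 10 samples", call. = FALSE)
  .with_seed(seed, {
    n_cal <- round(0.8 * M)
    cal_idx <- sort(sample.int(M, n_cal))
    val_idx <- setdiff(seq_len(M), cal_idx)
    model <- build_cnn(arch, ncol(ds$X), ncol(ds$Y))
    cfg <- training_config(learning_rate = learning_rate,
                           batch_size = batch_size,
                           max_epochs = max_epochs,
                           patience = max_epochs - 1L)
    out <- .cnn_train_loop(model, ds$X[cal_idx, , drop = FALSE],
                           ds$Y[cal_idx, , drop = FALSE],
                           ds$X[val_idx, , drop = FALSE],
                           ds$Y[val_idx, , drop = FALSE],
                           cfg, early_stop = FALSE)
    list(model = out$model, history = out$history,
         best_epoch = out$best_epoch, cal_idx = cal_idx)
  })
}
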