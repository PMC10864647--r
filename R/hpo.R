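#' Hyperparameter search space for the CNN + augmentation workflow
#'
#' Ranges follow the standard search design: 1-3 convolutional layers,
#' 1-10 filters per layer, odd filter widths from 3 up to a per-layer cap
#' that halves with each additional layer (because of the interposed
#' pooling layers), 5-100 fully connected units, dropout 0-0.3, L2 factor
#' log-uniform on 1e-9..1e-3, and a data-set-dependent range for the local
#' subset size.
#'
#' @param n_wavelengths input spectrum length (bounds the first-layer
#'   filter width).
#' @param n_lsa_range integer range (min, max) for the local subset size,
#'   e.g. `c(initial - 5, initial + 5)` around a tuned initial value.
#' @param n_conv_range candidate numbers of convolutional layers.
#' @param n_filters_range candidate filter counts per layer.
#' @param fc_units_range candidate fully-connected unit counts.
#' @param dropout_range continuous dropout interval.
#' @param l2_range log-uniform L2 interval.
#' @return Object of class `hpo_search_space`.
#' @export
hpo_search_space <- function(n_wavelengths, n_lsa_range,
                             n_conv_range = 1:3, n_filters_range = 1:10,
                             fc_units_range = c(5L, 100L),
                             dropout_range = c(0, 0.3),
                             l2_range = c(1e-9, 1e-3)) {
  stopifnot(length(n_lsa_range) == 2L, n_lsa_range[1] >= 1,
            n_lsa_range[2] >= n_lsa_range[1])
  caps <- integer(max(n_conv_range))
  cap <- as.integer(n_wavelengths)
  if (cap %% 2L == 0L) cap <- cap - 1L
  for (l in seq_along(caps)) {
    caps[l] <- max(3L, cap)
    cap <- cap %/% 2L
    if (cap %% 2L == 0L) cap <- cap - 1L
  }
  structure(
    list(n_wavelengths = as.integer(n_wavelengths),
         n_lsa_range = as.integer(n_lsa_range),
         n_conv_range = as.integer(n_conv_range),
         n_filters_range = as.integer(n_filters_range),
         width_caps = caps,
         fc_units_range = as.integer(fc_units_range),
         dropout_range = dropout_range, l2_range = l2_range),
    class = "hpo_search_space"
  )
}

# Draw one parameter set from the space using the current RNG stream.
# Conditional parameters (per-layer filters/widths) exist only for the
# sampled number of layers; widths respect both the halving cap and the
# running feature length.
.sample_trial_params <- function(space) {
  n_conv <- .resample(space$n_conv_range, 1L)
  widths <- integer(n_conv)
  filters <- integer(n_conv)
  L <- space$n_wavelengths
  for (l in seq_len(n_conv)) {
    # widths must leave at least one pooled feature (layers 1-2 halve);
    # when the feature length cannot host another layer, stop stacking
    cap <- min(space$width_caps[l], if (l <= 2L) L - 1L else L)
    if (cap < 3L) {
      n_conv <- l - 1L
      length(widths) <- n_conv
      length(filters) <- n_conv
      break
    }
    cand <- seq(3L, max(3L, cap), by = 2L)
    widths[l] <- .resample(cand, 1L)
    filters[l] <- .resample(space$n_filters_range, 1L)
    L <- L - widths[l] + 1L
    if (l <= 2L) L <- L %/% 2L
  }
  list(
    n_conv_layers = n_conv, n_filters = filters, filter_width = widths,
    fc_units = .resample(seq(space$fc_units_range[1],
                             space$fc_units_range[2]), 1L),
    dropout_rate = stats::runif(1L, space$dropout_range[1],
                                space$dropout_range[2]),
    l2_factor = 10^stats::runif(1L, log10(space$l2_range[1]),
                                log10(space$l2_range[2])),
    n_lsa = .resample(seq(space$n_lsa_range[1], space$n_lsa_range[2]), 1L)
  )
}

# sample() that treats a length-1 vector as a single candidate.
.resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

#' Median-pruning decision for one trial
#'
#' Before `activation_after` trials have completed, every trial is kept.
#' Afterwards a trial is pruned when its intermediate objective (the
#' training-data sum of per-component R-squared) is strictly lower than
#' the median of all previously reported intermediate values. Pruned
#' trials skip cross-validation entirely.
#'
#' @param value the trial's intermediate objective.
#' @param history previously reported intermediate objectives.
#' @param n_completed number of previously completed (non-pruned) trials;
#'   defaults to `length(history)`.
#' @param activation_after completed-trial count before pruning activates,
#'   default 100.
#' @return `"keep"` or `"prune"`.
#' @export
#' @examples
#' median_prune_decision(1.9, c(1, 2, 3), activation_after = 0) # prune
#' median_prune_decision(2.0, c(1, 2, 3), activation_after = 0) # keep
median_prune_decision <- function(value, history,
                                  n_completed = length(history),
                                  activation_after = 100L) {
  if (n_completed < activation_after || length(history) == 0L) return("keep")
  if (value < stats::median(history)) "prune" else "keep"
}

#' Run a hyperparameter-optimization study
#'
#' Per trial: a parameter set (architecture plus local subset size) is
#' sampled, the model is trained once on in-silico data generated from the
#' full training set to obtain the intermediate objective (training sum of
#' R-squared), the median-pruning rule is applied, and surviving trials are
#' scored by leave-one-group-out cross-validation (objective: sum of
#' per-component cross-validated R-squared). Trial-level failures are
#' recorded as failed trials and the study continues. Records are appended
#' incrementally as JSON lines when `record_path` is given.
#'
#' The `"tpe"` sampler denotes the Bayesian phase that follows the random
#' phase; no tree-structured Parzen estimator backend ships with this
#' package, so `"tpe"` currently continues with the seeded random sampler
#' and notes this once per study.
#'
#' @param ds a [spectral_dataset()] with at least 2 groups.
#' @param space an [hpo_search_space()].
#' @param n_trials number of trials, default 500.
#' @param sampler `"random"` or `"tpe"`.
#' @param seed integer seed; all trial randomness derives from it.
#' @param lsa_base an [lsa_config()] providing the non-searched
#'   augmentation settings (including `n_gen`).
#' @param train_cfg a [training_config()].
#' @param activation_after pruning activation threshold, default 100.
#' @param random_phase trials before the sampler switch, default 100.
#' @param record_path optional JSON-lines output path.
#' @return Object of class `hpo_study`: list with `records` (one
#'   data.frame row per trial), `trials` (full parameter sets), `best`
#'   (best completed trial) and the study settings.
#' @export
run_hpo_study <- function(ds, space, n_trials = 500L,
                          sampler = c("random", "tpe"), seed = NULL,
                          lsa_base = lsa_config(n_gen = 1000L),
                          train_cfg = training_config(),
                          activation_after = 100L, random_phase = 100L,
                          record_path = NULL) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(ds, "spectral_dataset"),
            inherits(space, "hpo_search_space"))
  if (sampler == "tpe") {
    message("No TPE backend is available; the post-random phase continues ",
            "with the seeded random sampler.")
  }
  trial_seeds <- .with_seed(seed, sample.int(2147483646L, n_trials))
  records <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  train_history <- numeric(0)
  n_completed <- 0L
  cv_calls <- 0L
  for (t in seq_len(n_trials)) {
    params <- .with_seed(trial_seeds[t], .sample_trial_params(space))
    trials[[t]] <- params
    rec <- tryCatch({
      arch <- cnn_architecture(
        n_conv_layers = params$n_conv_layers, n_filters = params$n_filters,
        filter_width = params$filter_width, fc_units = params$fc_units,
        dropout_rate = params$dropout_rate, l2_factor = params$l2_factor)
      lsa_t <- lsa_base
      lsa_t$n_lsa <- params$n_lsa
      lsa_t$seed <- .child_seed(trial_seeds[t], 1L)
      aug <- augment_dataset(ds, lsa_t)
      model <- build_cnn(arch, ncol(ds$X), ncol(ds$Y),
                         seed = .child_seed(trial_seeds[t], 2L))
      cfg_t <- train_cfg
      cfg_t$seed <- .child_seed(trial_seeds[t], 3L)
      tr <- train_cnn(model, aug$X_star, aug$Y_star, ds$X, ds$Y, cfg_t)
      m_train <- compute_metrics(ds$Y, predict_cnn(tr$model, ds$X))
      sum_r2_train <- sum(m_train$r2)
      decision <- median_prune_decision(sum_r2_train, train_history,
                                        n_completed, activation_after)
      train_history <- c(train_history, sum_r2_train)
      if (decision == "prune") {
        list(trial = t, status = "pruned", sum_r2_train = sum_r2_train,
             objective = NA_real_)
      } else {
        cv_t <- train_cfg
        cv_t$seed <- .child_seed(trial_seeds[t], 4L)
        cv <- cross_validate_cnn(ds, arch, lsa_t, cv_t)
        cv_calls <- cv_calls + 1L
        n_completed <- n_completed + 1L
        list(trial = t, status = "completed", sum_r2_train = sum_r2_train,
             objective = cv$objective)
      }
    }, error = function(e) {
      list(trial = t, status = "failed", sum_r2_train = NA_real_,
           objective = NA_real_, message = conditionMessage(e))
    })
    rec$sampler_phase <- if (t <= random_phase) "random" else sampler
    records[[t]] <- rec
    if (!is.null(record_path)) {
      line <- jsonlite::toJSON(c(rec, list(params = params)),
                               auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = record_path, append = t > 1L)
    }
  }
  rec_df <- do.call(rbind, lapply(records, function(r) {
    data.frame(trial = r$trial, status = r$status,
               sum_r2_train = r$sum_r2_train, objective = r$objective,
               sampler_phase = r$sampler_phase,
               stringsAsFactors = FALSE)
  }))
  completed <- rec_df[rec_df$status == "completed", , drop = FALSE]
  best <- if (nrow(completed)) {
    b <- completed[which.max(completed$objective), ]
    list(trial = b$trial, objective = b$objective,
         params = trials[[b$trial]])
  } else {
    NULL
  }
  structure(
    list(records = rec_df, trials = trials, best = best,
         cv_calls = cv_calls, seed = seed, sampler = sampler,
         lsa_base = lsa_base, train_cfg = train_cfg),
    class = "hpo_study"
  )
}

#' @export
print.hpo_study <- function(x, ...) {
  tab <- table(x$records$status)
  cat("<hpo_study> ", nrow(x$records), " trials (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  if (!is.null(x$best)) {
    cat("  best objective ", format(x$best$objective), " at trial ",
        x$best$trial, "\n", sep = "")
  }
  invisible(x)
}

#' Select the best study configuration and retrain it repeatedly
#'
#' Ranks completed trials by objective, exposes the top-k table for
#' inspection, and retrains the best configuration `repeats` times with a
#' modified patience of 10 and fresh seeds. Per-repeat metrics are reported
#' on the training data and, when supplied, on an independent test set.
#'
#' @param study an [run_hpo_study()] result.
#' @param ds the training [spectral_dataset()].
#' @param top_k size of the inspection table, default 5.
#' @param repeats retraining repetitions, default 10.
#' @param patience early-stopping patience for retraining, default 10.
#' @param test_ds optional held-out [spectral_dataset()].
#' @param seed integer seed for the retraining repetitions.
#' @return List with `top` (top-k trial table), `models` (list of trained
#'   models) and `metrics` (one data.frame row per repeat and subset with
#'   per-component NRMSE and R-squared).
#' @export
select_and_retrain <- function(study, ds, top_k = 5L, repeats = 10L,
                               patience = 10L, test_ds = NULL, seed = NULL) {
  stopifnot(inherits(study, "hpo_study"))
  completed <- study$records[study$records$status == "completed", ,
                             drop = FALSE]
  if (nrow(completed) < 1L) stop("no completed trials", call. = FALSE)
  ord <- order(-completed$objective)
  top <- completed[ord[seq_len(min(top_k, nrow(completed)))], ]
  best_params <- study$trials[[top$trial[1L]]]
  arch <- cnn_architecture(
    n_conv_layers = best_params$n_conv_layers,
    n_filters = best_params$n_filters,
    filter_width = best_params$filter_width,
    fc_units = best_params$fc_units,
    dropout_rate = best_params$dropout_rate,
    l2_factor = best_params$l2_factor)
  lsa_cfg <- study$lsa_base
  lsa_cfg$n_lsa <- best_params$n_lsa
  base_cfg <- study$train_cfg
  cfg <- training_config(learning_rate = base_cfg$learning_rate,
                         batch_size = base_cfg$batch_size,
                         max_epochs = max(base_cfg$max_epochs, patience + 1L),
                         patience = patience)
  models <- vector("list", repeats)
  rows <- list()
  for (r in seq_len(repeats)) {
    seed_r <- .child_seed(if (is.null(seed)) 0L else seed, r)
    lsa_r <- lsa_cfg
    lsa_r$seed <- .child_seed(seed_r, 1L)
    aug <- augment_dataset(ds, lsa_r)
    model <- build_cnn(arch, ncol(ds$X), ncol(ds$Y),
                       seed = .child_seed(seed_r, 2L))
    cfg_r <- cfg
    cfg_r$seed <- .child_seed(seed_r, 3L)
    tr <- train_cnn(model, aug$X_star, aug$Y_star, ds$X, ds$Y, cfg_r)
    models[[r]] <- tr$model
    subsets <- list(train = ds)
    if (!is.null(test_ds)) subsets$test <- test_ds
    for (nm in names(subsets)) {
      m <- compute_metrics(subsets[[nm]]$Y,
                           predict_cnn(tr$model, subsets[[nm]]$X),
                           subsets[[nm]]$component_names)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, subset = nm,
        component = names(m$nrmse), nrmse = unname(m$nrmse),
        r2 = unname(m$r2), stringsAsFactors = FALSE)
    }
  }
  list(top = top, arch = arch, models = models,
       metrics = do.call(rbind, rows))
}
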