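#' Perturbation grid for the in-silico robustness study
#'
#' Default levels are the white-noise SDs {0.001, 0.005, 0.01, 0.05, 0.1,
#' 0.5, 1} (absorbance units) and wavelength-shift SDs {0, 0.05, 0.1,
#' 0.15, 0.2, 0.25, 0.3} (wavelength units); the two axes are varied one
#' at a time.
#'
#' @param noise_levels white-noise SDs (>= 0).
#' @param shift_levels wavelength-shift SDs (>= 0).
#' @param seeds integer seeds; the study is repeated per seed.
#' @return Object of class `robustness_grid`.
#' @export
robustness_grid <- function(noise_levels = c(0.001, 0.005, 0.01, 0.05, 0.1,
                                             0.5, 1),
                            shift_levels = c(0, 0.05, 0.1, 0.15, 0.2, 0.25,
                                             0.3),
                            seeds = 1L) {
  if (any(noise_levels < 0) || any(shift_levels < 0)) {
    stop("perturbation levels must be >= 0", call. = FALSE)
  }
  if (length(noise_levels) + length(shift_levels) == 0L) {
    stop("grid must contain at least one level", call. = FALSE)
  }
  structure(list(noise_levels = noise_levels, shift_levels = shift_levels,
                 seeds = as.integer(seeds)),
            class = "robustness_grid")
}

#' Perturb the spectra of a generated data set
#'
#' Applies [perturb_spectrum()] to every generated spectrum (one shift
#' draw per spectrum, i.i.d. noise per feature); concentrations are left
#' unchanged.
#'
#' @param aug an [augment_dataset()] result.
#' @param sigma_noise white-noise SD.
#' @param sigma_shift wavelength-shift SD.
#' @param seed optional integer seed.
#' @return A perturbed `augmented_dataset`.
#' @export
perturb_generated <- function(aug, sigma_noise, sigma_shift, seed = NULL) {
  stopifnot(inherits(aug, "augmented_dataset"))
  if (sigma_noise == 0 && sigma_shift == 0) return(aug)
  aug$X_star <- .with_seed(seed, .perturb_matrix(aug$X_star, aug$wavelengths,
                                                 sigma_noise, sigma_shift))
  aug$perturbation <- list(sigma_noise = sigma_noise,
                           sigma_shift = sigma_shift, seed = seed)
  aug
}

.perturb_matrix <- function(X, wavelengths, sigma_noise, sigma_shift) {
  out <- X
  for (i in seq_len(nrow(X))) {
    out[i, ] <- perturb_spectrum(X[i, ], wavelengths, sigma_noise,
                                 sigma_shift)
  }
  out
}

#' In-silico noise/shift robustness study
#'
#' Compares two handling modes per perturbation level: `"fixed"` models
#' are trained once on the unperturbed generated data and evaluated on
#' perturbed evaluation spectra; `"retrained"` models are trained on
#' generated data perturbed at the level under test (and evaluated on the
#' same perturbed evaluation spectra). The per-cell summary is the sum of
#' per-component NRMSE on the evaluation data. Noise and shift axes are
#' swept separately.
#'
#' @param ds training [spectral_dataset()]; also the evaluation data
#'   unless `eval_ds` is given.
#' @param cnn_arch a [cnn_architecture()] or `NULL` to skip the CNN.
#' @param lsa_cfg an [lsa_config()] (its `n_gen` sets the generated-set
#'   size).
#' @param pls_cfgs per-component list of `list(A =, sgf =)` PLS settings,
#'   a single such list recycled to all components, or `NULL` to skip the
#'   PLS models. PLS models are trained on the same generated data as the
#'   CNN.
#' @param grid a [robustness_grid()].
#' @param train_cfg a [training_config()] for the CNN.
#' @param modes subset of `c("fixed", "retrained")`.
#' @param eval_ds optional separate evaluation [spectral_dataset()].
#' @return Long-format data.frame with columns `model`, `mode`, `axis`,
#'   `level`, `seed`, `sum_nrmse` plus per-component NRMSE columns.
#' @export
run_robustness_study <- function(ds, cnn_arch, lsa_cfg, pls_cfgs = NULL,
                                 grid = robustness_grid(),
                                 train_cfg = training_config(),
                                 modes = c("fixed", "retrained"),
                                 eval_ds = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(grid, "robustness_grid"))
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(eval_ds)) eval_ds <- ds
  P <- ncol(ds$Y)
  if (!is.null(pls_cfgs) && !is.null(pls_cfgs$A)) {
    pls_cfgs <- rep(list(pls_cfgs), P)
  }
  cells <- rbind(
    if (length(grid$noise_levels)) {
      data.frame(axis = "noise", level = grid$noise_levels)
    },
    if (length(grid$shift_levels)) {
      data.frame(axis = "shift", level = grid$shift_levels)
    }
  )
  step <- ds$wavelengths[2] - ds$wavelengths[1]

  train_models <- function(aug, seed) {
    out <- list()
    if (!is.null(cnn_arch)) {
      model <- build_cnn(cnn_arch, ncol(ds$X), P, seed = .child_seed(seed, 21L))
      cfg <- train_cfg
      cfg$seed <- .child_seed(seed, 22L)
      out$cnn <- train_cnn(model, aug$X_star, aug$Y_star, ds$X, ds$Y,
                           cfg)$model
    }
    if (!is.null(pls_cfgs)) {
      out$pls <- lapply(seq_len(P), function(p) {
        fit_pls1(aug$X_star, aug$Y_star[, p], pls_cfgs[[p]]$A,
                 sgf = pls_cfgs[[p]]$sgf, wavelength_step = step)
      })
    }
    out
  }
  eval_models <- function(models, X_eval) {
    rows <- list()
    if (!is.null(models$cnn)) {
      m <- compute_metrics(eval_ds$Y, predict_cnn(models$cnn, X_eval),
                           eval_ds$component_names)
      rows$cnn <- m$nrmse
    }
    if (!is.null(models$pls)) {
      pred <- vapply(seq_len(P), function(p) {
        predict_pls1(models$pls[[p]], X_eval)
      }, numeric(nrow(X_eval)))
      m <- compute_metrics(eval_ds$Y, pred, eval_ds$component_names)
      rows$pls <- m$nrmse
    }
    rows
  }

  results <- list()
  for (seed in grid$seeds) {
    lsa_s <- lsa_cfg
    lsa_s$seed <- .child_seed(seed, 1L)
    aug0 <- augment_dataset(ds, lsa_s)
    fixed_models <- if ("fixed" %in% modes) train_models(aug0, seed) else NULL
    for (ci in seq_len(nrow(cells))) {
      axis <- cells$axis[ci]
      level <- cells$level[ci]
      sn <- if (axis == "noise") level else 0
      ss <- if (axis == "shift") level else 0
      X_eval <- .with_seed(.child_seed(seed, 100L + ci),
                           .perturb_matrix(eval_ds$X, eval_ds$wavelengths,
                                           sn, ss))
      for (mode in modes) {
        models <- if (mode == "fixed") {
          fixed_models
        } else {
          aug_v <- perturb_generated(aug0, sn, ss,
                                     seed = .child_seed(seed, 200L + ci))
          train_models(aug_v, .child_seed(seed, 300L + ci))
        }
        ev <- eval_models(models, X_eval)
        for (nm in names(ev)) {
          row <- data.frame(model = nm, mode = mode, axis = axis,
                            level = level, seed = seed,
                            sum_nrmse = sum(ev[[nm]]),
                            stringsAsFactors = FALSE)
          for (p in seq_len(P)) {
            row[[paste0("nrmse_", eval_ds$component_names[p])]] <- ev[[nm]][p]
          }
          results[[length(results) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, results)
}
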