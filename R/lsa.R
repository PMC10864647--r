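#' Configuration of the local subset augmentation (LSA) method
#'
#' Defaults are the base settings of the augmentation workflow: subset size
#' 5, Euclidean distance, NNLS solver, white-noise SD 0.001 (stored
#' absorbance units), wavelength-shift SD 0.01 (wavelength units), 1e5
#' generated samples, KDE concentration sampling.
#'
#' @param n_lsa local subset size (>= 1).
#' @param norm_order order of the vector norm for the concentration
#'   distance, 1 or 2.
#' @param solver `"nnls"` or `"ols"` for pure-component estimation.
#' @param sigma_noise white-noise SD added per feature (same units as the
#'   stored absorbance).
#' @param sigma_shift SD of the per-spectrum wavelength shift (wavelength
#'   units).
#' @param n_gen number of spectra to generate.
#' @param sampler_mode `"kde"`, `"uniform"` or `"normal"`.
#' @param seed optional integer seed for [augment_dataset()].
#' @return Object of class `lsa_config`.
#' @export
lsa_config <- function(n_lsa = 5L, norm_order = 2, solver = c("nnls", "ols"),
                       sigma_noise = 0.001, sigma_shift = 0.01,
                       n_gen = 1e5, sampler_mode = c("kde", "uniform", "normal"),
                       seed = NULL) {
  solver <- match.arg(solver)
  sampler_mode <- match.arg(sampler_mode)
  if (!.is_count(n_lsa)) stop("n_lsa must be a positive integer", call. = FALSE)
  if (!norm_order %in% c(1, 2)) stop("norm_order must be 1 or 2", call. = FALSE)
  if (!.is_count(n_gen)) stop("n_gen must be a positive integer", call. = FALSE)
  if (sigma_noise < 0 || sigma_shift < 0) {
    stop("sigma_noise and sigma_shift must be >= 0", call. = FALSE)
  }
  structure(
    list(n_lsa = as.integer(n_lsa), norm_order = norm_order, solver = solver,
         sigma_noise = sigma_noise, sigma_shift = sigma_shift,
         n_gen = as.integer(n_gen), sampler_mode = sampler_mode,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "lsa_config"
  )
}

#' @export
print.lsa_config <- function(x, ...) {
  cat("<lsa_config> n_lsa=", x$n_lsa, ", l=", x$norm_order, ", solver=",
      x$solver, ", sigma_noise=", x$sigma_noise, ", sigma_shift=",
      x$sigma_shift, ", n_gen=", x$n_gen, ", sampler=", x$sampler_mode,
      "\n", sep = "")
  invisible(x)
}

#' Select the local subset nearest a sampled concentration vector
#'
#' Returns the indices of the `n_lsa` rows of `Y` with the smallest
#' `l`-norm distance to `y_star`, in ascending-distance order; ties are
#' broken by ascending row index.
#'
#' @param Y concentration matrix, M x P.
#' @param y_star concentration vector of length P.
#' @param n_lsa subset size, at most M.
#' @param norm_order distance norm order, 1 or 2.
#' @return Integer vector of `n_lsa` row indices.
#' @export
#' @examples
#' Y <- matrix(c(3, 0, 2, 2), 2, byrow = TRUE)
#' select_local_subset(Y, c(0, 0), 1, norm_order = 1) # row 1 (distance 3)
#' select_local_subset(Y, c(0, 0), 1, norm_order = 2) # row 2 (~2.83)
select_local_subset <- function(Y, y_star, n_lsa, norm_order = 2) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  M <- nrow(Y)
  if (n_lsa > M) {
    stop("n_lsa (", n_lsa, ") exceeds the number of available samples (",
         M, ")", call. = FALSE)
  }
  if (!norm_order %in% c(1, 2)) stop("norm_order must be 1 or 2", call. = FALSE)
  D <- abs(sweep(Y, 2L, as.numeric(y_star)))
  d <- if (norm_order == 1) rowSums(D) else sqrt(rowSums(D^2))
  order(d, seq_len(M))[seq_len(n_lsa)]
}

#' Perturb a spectrum by wavelength shift and white noise
#'
#' One shift `delta ~ N(0, sigma_shift)` is drawn per spectrum and the
#' spectrum is re-evaluated at `wavelengths - delta` by linear interpolation
#' with boundary values held (nearest extrapolation); i.i.d. Gaussian noise
#' `N(0, sigma_noise)` is then added per feature. The shift is applied
#' before the noise so the noise statistics are unaffected by the shift.
#' Draws come from the current RNG stream; seed at the call site for
#' reproducibility.
#'
#' @param x spectrum of length N.
#' @param wavelengths axis of length N.
#' @param sigma_noise white-noise SD (>= 0).
#' @param sigma_shift shift SD (>= 0, wavelength units).
#' @param delta optional fixed shift overriding the random draw (used by
#'   diagnostics).
#' @return Perturbed spectrum of length N.
#' @export
perturb_spectrum <- function(x, wavelengths, sigma_noise, sigma_shift,
                             delta = NULL) {
  if (sigma_noise < 0 || sigma_shift < 0) {
    stop("sigma values must be >= 0", call. = FALSE)
  }
  x <- as.numeric(x)
  N <- length(x)
  if (length(wavelengths) != N) stop("axis length mismatch", call. = FALSE)
  if (is.null(delta)) {
    delta <- if (sigma_shift > 0) stats::rnorm(1L, 0, sigma_shift) else 0
  }
  if (delta != 0) {
    x <- stats::approx(wavelengths, x, xout = wavelengths - delta,
                       rule = 2)$y
  }
  if (sigma_noise > 0) x <- x + stats::rnorm(N, 0, sigma_noise)
  x
}

#' Generate an augmented data set by local subset augmentation
#'
#' For each of `n_gen` draws: sample a concentration vector from the fitted
#' per-component sampler, select the `n_lsa` experimentally measured
#' samples nearest in concentration space, estimate pure-component profiles
#' from that local subset, synthesize the mixture spectrum, and perturb it
#' by wavelength shift and white noise. Deterministic under `cfg$seed`.
#'
#' @param ds a [spectral_dataset()] (the training data).
#' @param cfg an [lsa_config()] with `n_lsa <= nrow(ds$X)`.
#' @return Object of class `augmented_dataset` with `X_star`
#'   (`n_gen` x N generated spectra), `Y_star` (`n_gen` x P sampled
#'   concentrations), `config` and a `provenance` fingerprint of the source
#'   data.
#' @export
augment_dataset <- function(ds, cfg) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "lsa_config"))
  M <- nrow(ds$X)
  if (cfg$n_lsa > M) {
    stop("n_lsa (", cfg$n_lsa, ") exceeds the training set size (", M, ")",
         call. = FALSE)
  }
  N <- ncol(ds$X)
  run <- function() {
    sampler <- fit_sampler(ds$Y, cfg$sampler_mode)
    Y_star <- sample_concentrations(sampler, cfg$n_gen)
    X_star <- matrix(0, cfg$n_gen, N)
    for (g in seq_len(cfg$n_gen)) {
      res <- tryCatch({
        idx <- select_local_subset(ds$Y, Y_star[g, ], cfg$n_lsa,
                                   cfg$norm_order)
        S <- estimate_pure_components(ds$X[idx, , drop = FALSE],
                                      ds$Y[idx, , drop = FALSE],
                                      solver = cfg$solver,
                                      wavelengths = ds$wavelengths)
        x <- synthesize_spectrum(S, Y_star[g, ])
        perturb_spectrum(x, ds$wavelengths, cfg$sigma_noise, cfg$sigma_shift)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        stop("generation ", g, ": ", conditionMessage(res), call. = FALSE)
      }
      X_star[g, ] <- res
    }
    list(X_star = X_star, Y_star = Y_star)
  }
  out <- .with_seed(cfg$seed, run())
  colnames(out$Y_star) <- ds$component_names
  structure(
    list(X_star = out$X_star, Y_star = out$Y_star, config = cfg,
         wavelengths = ds$wavelengths, component_names = ds$component_names,
         provenance = list(M = M, N = N, P = ncol(ds$Y),
                           x_checksum = sum(ds$X), y_checksum = sum(ds$Y))),
    class = "augmented_dataset"
  )
}

#' @export
print.augmented_dataset <- function(x, ...) {
  cat("<augmented_dataset> ", nrow(x$X_star), " generated spectra x ",
      ncol(x$X_star), " wavelengths (", ncol(x$Y_star), " components)\n",
      sep = "")
  invisible(x)
}

#' Cross-validated spectral reconstruction error of an LSA configuration
#'
#' Leave-one-group-out reconstruction: for every held-out sample, the local
#' subset is selected and pure-component profiles are estimated from the
#' retained groups only; the spectrum synthesized at the held-out sample's
#' measured concentrations (without noise/shift perturbation unless
#' `apply_perturbation = TRUE`) is compared with the measured spectrum. The
#' summary is the root of the mean squared residual over all held-out
#' samples and wavelengths.
#'
#' @param ds a [spectral_dataset()] with at least 2 groups.
#' @param cfg an [lsa_config()]; `n_gen` and the sampler are not used here.
#' @param apply_perturbation also apply the configured noise/shift to the
#'   reconstruction before computing residuals (default `FALSE`).
#' @param pooling `"pooled"` (default; RMSE over all pooled residuals) or
#'   `"averaged"` (mean of per-rotation RMSEs).
#' @return List with `rmsecv` (scalar), `residuals` (M x N matrix,
#'   synthesized minus measured, rows in original sample order) and
#'   `per_group` (named per-rotation RMSE vector).
#' @export
reconstruction_cv <- function(ds, cfg, apply_perturbation = FALSE,
                              pooling = c("pooled", "averaged")) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "lsa_config"))
  pooling <- match.arg(pooling)
  groups <- unique(ds$groups)
  if (length(groups) < 2L) {
    stop("reconstruction CV needs at least 2 groups", call. = FALSE)
  }
  R <- matrix(NA_real_, nrow(ds$X), ncol(ds$X))
  per_group <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    held <- which(ds$groups == g)
    kept <- which(ds$groups != g)
    if (length(kept) < cfg$n_lsa) {
      stop("rotation '", g, "': retained data (", length(kept),
           " samples) smaller than n_lsa (", cfg$n_lsa, ")", call. = FALSE)
    }
    Yk <- ds$Y[kept, , drop = FALSE]
    Xk <- ds$X[kept, , drop = FALSE]
    for (i in held) {
      idx <- select_local_subset(Yk, ds$Y[i, ], cfg$n_lsa, cfg$norm_order)
      S <- estimate_pure_components(Xk[idx, , drop = FALSE],
                                    Yk[idx, , drop = FALSE],
                                    solver = cfg$solver,
                                    wavelengths = ds$wavelengths)
      xhat <- synthesize_spectrum(S, ds$Y[i, ])
      if (apply_perturbation) {
        xhat <- perturb_spectrum(xhat, ds$wavelengths, cfg$sigma_noise,
                                 cfg$sigma_shift)
      }
      R[i, ] <- xhat - ds$X[i, ]
    }
    per_group[g] <- sqrt(mean(R[held, , drop = FALSE]^2))
  }
  rmsecv <- switch(pooling,
                   pooled = sqrt(mean(R^2)),
                   averaged = mean(per_group))
  list(rmsecv = rmsecv, residuals = R, per_group = per_group)
}

#' Grid tuning of the LSA hyperparameters by reconstruction error
#'
#' Exhaustively evaluates [reconstruction_cv()] over the Cartesian product
#' of the supplied value lists and returns the configuration minimizing the
#' cross-validated reconstruction RMSE. Ties are broken by smaller
#' `n_lsa`, then `norm_order` 2 before 1, then listing order.
#'
#' @param ds a [spectral_dataset()] with at least 2 groups.
#' @param grid named list of value vectors over any subset of `n_lsa`,
#'   `norm_order`, `solver`, `sigma_noise`, `sigma_shift`; parameters not
#'   listed keep the [lsa_config()] defaults (or `base` values).
#' @param base an [lsa_config()] providing values for parameters outside
#'   the grid.
#' @param apply_perturbation passed to [reconstruction_cv()]; default
#'   `FALSE`, so noise/shift settings affect generation only.
#' @param pooling passed to [reconstruction_cv()].
#' @return List with `best_config` (an [lsa_config()]) and `results` (one
#'   data.frame row per grid point, with `rmsecv`).
#' @export
tune_lsa <- function(ds, grid, base = lsa_config(),
                     apply_perturbation = FALSE,
                     pooling = c("pooled", "averaged")) {
  pooling <- match.arg(pooling)
  allowed <- c("n_lsa", "norm_order", "solver", "sigma_noise", "sigma_shift")
  if (!is.list(grid) || length(grid) == 0L ||
      any(lengths(grid) == 0L) || is.null(names(grid)) ||
      !all(nzchar(names(grid)))) {
    stop("grid must be a non-empty named list of value vectors", call. = FALSE)
  }
  if (!all(names(grid) %in% allowed)) {
    stop("unknown grid parameter(s): ",
         paste(setdiff(names(grid), allowed), collapse = ", "), call. = FALSE)
  }
  full <- list(n_lsa = base$n_lsa, norm_order = base$norm_order,
               solver = base$solver, sigma_noise = base$sigma_noise,
               sigma_shift = base$sigma_shift)
  full[names(grid)] <- grid
  tab <- expand.grid(full, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tab$rmsecv <- NA_real_
  for (r in seq_len(nrow(tab))) {
    cfg <- lsa_config(n_lsa = tab$n_lsa[r], norm_order = tab$norm_order[r],
                      solver = tab$solver[r], sigma_noise = tab$sigma_noise[r],
                      sigma_shift = tab$sigma_shift[r],
                      n_gen = base$n_gen, sampler_mode = base$sampler_mode)
    tab$rmsecv[r] <- reconstruction_cv(ds, cfg, apply_perturbation,
                                       pooling)$rmsecv
  }
  ord <- order(tab$rmsecv, tab$n_lsa, -tab$norm_order, seq_len(nrow(tab)))
  b <- tab[ord[1L], ]
  best <- lsa_config(n_lsa = b$n_lsa, norm_order = b$norm_order,
                     solver = b$solver, sigma_noise = b$sigma_noise,
                     sigma_shift = b$sigma_shift, n_gen = base$n_gen,
                     sampler_mode = base$sampler_mode, seed = base$seed)
  list(best_config = best, results = tab)
}
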