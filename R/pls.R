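#' Savitzky-Golay filter configuration
#'
#' @param window odd window width in points, `>= 3` and greater than the
#'   polynomial order.
#' @param polyorder polynomial degree, default 2.
#' @param deriv derivative order 0, 1 or 2 (at most `polyorder`).
#' @return Object of class `sgf_config`.
#' @export
sgf_config <- function(window = 11L, polyorder = 2L, deriv = 0L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (deriv < 0L || deriv > polyorder) {
    stop("deriv must be between 0 and polyorder", call. = FALSE)
  }
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sgf_config")
}

#' Savitzky-Golay smoothing/differentiation of spectra
#'
#' Filters every row with a local least-squares polynomial fit
#' (edge points come from evaluating the boundary-window polynomial fits,
#' so an exact polynomial of degree `<= polyorder` is reproduced
#' everywhere). Derivatives are scaled by the wavelength step, so `deriv =
#' 1` returns d(absorbance)/d(wavelength).
#'
#' @param X spectra matrix M x N (or a single spectrum).
#' @param cfg an [sgf_config()].
#' @param wavelength_step grid spacing of the wavelength axis, default 1.
#' @return Filtered matrix of the same shape.
#' @export
sgf_preprocess <- function(X, cfg, wavelength_step = 1) {
  stopifnot(inherits(cfg, "sgf_config"))
  vec <- is.vector(X)
  if (vec) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) < cfg$window) {
    stop("window (", cfg$window, ") exceeds the number of wavelengths (",
         ncol(X), ")", call. = FALSE)
  }
  out <- t(apply(X, 1L, function(x) {
    signal::sgolayfilt(x, p = cfg$polyorder, n = cfg$window, m = cfg$deriv,
                       ts = wavelength_step)
  }))
  if (vec) out <- as.numeric(out)
  out
}

# Core PLS1 NIPALS on centered data. Returns weights W, x-loadings Pl,
# y-loadings q, scores Tt, and the regression coefficients for every
# truncation 1..A (column a of `betas` uses the first a components).
.pls1_nipals <- function(Xc, yc, A) {
  M <- nrow(Xc)
  N <- ncol(Xc)
  W <- matrix(0, N, A)
  Pl <- matrix(0, N, A)
  q <- numeric(A)
  Tt <- matrix(0, M, A)
  Xa <- Xc
  ya <- yc
  A_eff <- A
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yc^2)))) {
      # no covariance left between X and y: later components are void
      A_eff <- a - 1L
      break
    }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    qa <- sum(t * ya) / tt
    p <- crossprod(Xa, t) / tt
    Xa <- Xa - t %*% t(p)
    ya <- ya - qa * t
    W[, a] <- w
    Pl[, a] <- p
    q[a] <- qa
    Tt[, a] <- t
  }
  betas <- matrix(NA_real_, N, A)
  for (a in seq_len(A_eff)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- Pl[, seq_len(a), drop = FALSE]
    betas[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  list(W = W[, seq_len(A_eff), drop = FALSE],
       Pl = Pl[, seq_len(A_eff), drop = FALSE],
       q = q[seq_len(A_eff)], Tt = Tt[, seq_len(A_eff), drop = FALSE],
       betas = betas, A_eff = A_eff)
}

#' Fit a single-response PLS model by NIPALS
#'
#' Standard PLS1 with deflation: in each component the loading weight is
#' the normalized X'y covariance, scores and loadings follow, and X and y
#' are deflated. The regression vector is assembled as
#' `beta = W (P'W)^-1 q`, so predictions are
#' `(X - x_mean) beta + y_mean` on the (optionally Savitzky-Golay
#' preprocessed) spectra.
#'
#' @param X raw spectra matrix M x N.
#' @param y response vector of length M.
#' @param A number of PLS components, at most `min(M - 1, N)`.
#' @param sgf optional [sgf_config()]; when given, spectra are filtered
#'   before centering and the filter is stored for prediction.
#' @param wavelength_step grid spacing used for derivative scaling.
#' @return Object of class `pls1_model` with elements `A`, `W`, `Pl`, `q`,
#'   `Tt`, `beta`, `x_mean`, `y_mean`, `sgf`, `wavelength_step`.
#' @export
fit_pls1 <- function(X, y, A, sgf = NULL, wavelength_step = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  M <- nrow(X)
  N <- ncol(X)
  if (length(y) != M) stop("y length does not match nrow(X)", call. = FALSE)
  if (!.is_count(A) || A > min(M - 1L, N)) {
    stop("A must be a positive integer <= min(M - 1, N) = ",
         min(M - 1L, N), call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("zero-variance response", call. = FALSE)
  if (!is.null(sgf)) X <- sgf_preprocess(X, sgf, wavelength_step)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  fit <- .pls1_nipals(sweep(X, 2L, x_mean), y - y_mean, A)
  if (fit$A_eff < A) {
    stop("NIPALS collapsed at component ", fit$A_eff + 1L,
         ": no covariance left between X and y; request A <= ", fit$A_eff,
         call. = FALSE)
  }
  structure(
    list(A = as.integer(A), W = fit$W, Pl = fit$Pl, q = fit$q, Tt = fit$Tt,
         beta = fit$betas[, A], betas = fit$betas, x_mean = x_mean,
         y_mean = y_mean, sgf = sgf, wavelength_step = wavelength_step),
    class = "pls1_model"
  )
}

#' @export
print.pls1_model <- function(x, ...) {
  cat("<pls1_model> A=", x$A, ", N=", length(x$beta),
      if (!is.null(x$sgf)) paste0(", SGF(window=", x$sgf$window, ", deriv=",
                                  x$sgf$deriv, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Predict with a fitted PLS1 model
#'
#' Applies the stored preprocessing (Savitzky-Golay filter if configured,
#' then mean centering) and the regression vector.
#'
#' @param model a [fit_pls1()] result.
#' @param X_new spectra matrix M' x N (raw scale).
#' @param A optional smaller number of components to use (defaults to the
#'   fitted `model$A`).
#' @return Numeric predictions of length M'.
#' @export
predict_pls1 <- function(model, X_new, A = NULL) {
  stopifnot(inherits(model, "pls1_model"))
  if (is.vector(X_new)) X_new <- matrix(X_new, nrow = 1L)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean)) {
    stop("wavelength count mismatch: model has ", length(model$x_mean),
         ", data has ", ncol(X_new), call. = FALSE)
  }
  if (is.null(A)) A <- model$A
  if (A < 1L || A > model$A) stop("A out of fitted range", call. = FALSE)
  if (!is.null(model$sgf)) {
    X_new <- sgf_preprocess(X_new, model$sgf, model$wavelength_step)
  }
  beta <- model$betas[, A]
  as.numeric(sweep(X_new, 2L, model$x_mean) %*% beta + model$y_mean)
}

#' Grid search over PLS rank and Savitzky-Golay preprocessing
#'
#' Leave-one-group-out cross-validation over the grid of component counts,
#' derivative orders and odd smoothing windows; residuals are pooled over
#' rotations and scored by the scaled criterion of [sse_cv_scaled()]. Ties
#' are broken towards smaller `A`, then smaller window, then lower
#' derivative order.
#'
#' @param ds a [spectral_dataset()] with at least 2 groups.
#' @param component index (or name) of the response component.
#' @param a_values candidate component counts, default `1:10`.
#' @param deriv_values candidate derivative orders, default `0:2`.
#' @param window_values candidate odd windows, default `seq(3, 31, 2)`.
#' @return List with `best` (row of the winning configuration),
#'   `best_model` (a [fit_pls1()] refit on all samples), `results` (full
#'   table with `ssecv_scaled`, `rmsecv`, `r2cv` per configuration) and
#'   `cv_predictions` for the winning configuration.
#' @export
tune_pls <- function(ds, component, a_values = 1:10, deriv_values = 0:2,
                     window_values = seq(3L, 31L, 2L)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.character(component)) {
    component <- match(component, ds$component_names)
  }
  y <- ds$Y[, component]
  groups <- unique(ds$groups)
  if (length(groups) < 2L) stop("need at least 2 groups for CV", call. = FALSE)
  step <- ds$wavelengths[2] - ds$wavelengths[1]
  N <- ncol(ds$X)
  window_values <- window_values[window_values <= N]
  a_max <- max(a_values)
  results <- list()
  pred_store <- list()
  for (w in window_values) {
    for (d in deriv_values) {
      cfg <- sgf_config(window = w, deriv = d)
      Z <- sgf_preprocess(ds$X, cfg, step)
      preds <- matrix(NA_real_, nrow(Z), a_max)
      for (g in groups) {
        tr <- ds$groups != g
        a_fit <- min(a_max, sum(tr) - 1L, N)
        fit <- .pls1_nipals(sweep(Z[tr, , drop = FALSE], 2L,
                                  colMeans(Z[tr, , drop = FALSE])),
                            y[tr] - mean(y[tr]), a_fit)
        Zc <- sweep(Z[!tr, , drop = FALSE], 2L, colMeans(Z[tr, , drop = FALSE]))
        preds[!tr, seq_len(a_fit)] <- Zc %*% fit$betas + mean(y[tr])
      }
      for (a in a_values) {
        if (a > ncol(preds) || anyNA(preds[, a])) next
        resid <- preds[, a] - y
        results[[length(results) + 1L]] <- data.frame(
          A = a, deriv = d, window = w,
          ssecv_scaled = sse_cv_scaled(resid, a),
          rmsecv = sqrt(mean(resid^2)),
          r2cv = 1 - sum(resid^2) / sum((y - mean(y))^2)
        )
        pred_store[[paste(a, d, w)]] <- preds[, a]
      }
    }
  }
  tab <- do.call(rbind, results)
  ord <- order(tab$ssecv_scaled, tab$A, tab$window, tab$deriv)
  best <- tab[ord[1L], ]
  best_cfg <- sgf_config(window = best$window, deriv = best$deriv)
  best_model <- fit_pls1(ds$X, y, best$A, sgf = best_cfg,
                         wavelength_step = step)
  list(best = best, best_model = best_model, results = tab,
       cv_predictions = pred_store[[paste(best$A, best$deriv, best$window)]])
}
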