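#' Per-component regression metrics
#'
#' Computes root mean squared error (RMSE), normalized RMSE (RMSE divided by
#' the arithmetic mean of the observed values of that component) and the
#' coefficient of determination R-squared = 1 - SSres/SStot for each
#' component column.
#'
#' NRMSE is `NA` for a component whose observed mean is not positive, and
#' R-squared is `NA` when the observed values have zero variance; both cases
#' raise a warning.
#'
#' @param y_true observed concentration matrix (M x P) or vector.
#' @param y_pred predicted concentration matrix of the same shape.
#' @param component_names optional P labels for the output vectors.
#' @return An object of class `spectral_metrics`: list with numeric vectors
#'   `rmse`, `nrmse`, `r2` of length P.
#' @export
#' @examples
#' compute_metrics(c(1, 1), c(2, 2)) # RMSE 1, NRMSE 1
compute_metrics <- function(y_true, y_pred, component_names = NULL) {
  if (is.vector(y_true)) y_true <- matrix(y_true, ncol = 1L)
  if (is.vector(y_pred)) y_pred <- matrix(y_pred, ncol = 1L)
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("y_true and y_pred shapes differ", call. = FALSE)
  }
  if (nrow(y_true) < 1L) stop("at least one sample is required", call. = FALSE)
  P <- ncol(y_true)
  if (is.null(component_names)) {
    component_names <- colnames(y_true)
    if (is.null(component_names)) component_names <- paste0("comp", seq_len(P))
  }
  res <- y_pred - y_true
  rmse <- sqrt(colMeans(res^2))
  ybar <- colMeans(y_true)
  nrmse <- rep(NA_real_, P)
  pos <- ybar > 0
  nrmse[pos] <- rmse[pos] / ybar[pos]
  if (any(!pos)) {
    warning("NRMSE undefined for component(s) with non-positive mean: ",
            paste(component_names[!pos], collapse = ", "), call. = FALSE)
  }
  sstot <- colSums(sweep(y_true, 2L, ybar)^2)
  r2 <- rep(NA_real_, P)
  varying <- sstot > 0
  r2[varying] <- 1 - colSums(res^2)[varying] / sstot[varying]
  if (any(!varying)) {
    warning("R2 undefined for zero-variance component(s): ",
            paste(component_names[!varying], collapse = ", "), call. = FALSE)
  }
  names(rmse) <- names(nrmse) <- names(r2) <- component_names
  structure(list(rmse = rmse, nrmse = nrmse, r2 = r2),
            class = "spectral_metrics")
}

#' @export
print.spectral_metrics <- function(x, ...) {
  cat("<spectral_metrics>\n")
  print(data.frame(rmse = x$rmse, nrmse = x$nrmse, r2 = x$r2))
  invisible(x)
}

#' Cross-validated scaled sum of squared errors
#'
#' The model-selection criterion for PLS: the sum of squared CV residuals
#' divided by `M - n_pls - 1`, where `M` is the number of pooled
#' cross-validation predictions and `n_pls` the number of PLS components.
#' Penalizes model complexity through the denominator.
#'
#' @param residuals numeric vector of predicted-minus-observed values pooled
#'   over all cross-validation rotations.
#' @param n_pls number of PLS components of the candidate model.
#' @return Scalar criterion value.
#' @export
#' @examples
#' sse_cv_scaled(c(1, 1, 1, 1), 2) # 4 / (4 - 2 - 1) = 4
sse_cv_scaled <- function(residuals, n_pls) {
  residuals <- as.numeric(residuals)
  M <- length(residuals)
  n_pls <- as.integer(n_pls)
  if (M - n_pls - 1L <= 0L) {
    stop("degrees of freedom exhausted: M = ", M, ", n_pls = ", n_pls,
         call. = FALSE)
  }
  sum(residuals^2) / (M - n_pls - 1L)
}
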