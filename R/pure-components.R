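#' Pure-component absorbance profiles
#'
#' An N x P matrix of absorbance-per-unit-concentration estimates: column p
#' is the spectrum one concentration unit of component p contributes under
#' the Beer-Lambert mixing model.
#'
#' @param S numeric N x P matrix with finite entries.
#' @param wavelengths optional axis of length N.
#' @param scope `"local"` (estimated from a local concentration
#'   neighborhood) or `"global"` (estimated from, or defined on, the whole
#'   data set).
#' @return Object of class `pure_component_profiles`.
#' @export
pure_component_profiles <- function(S, wavelengths = NULL,
                                    scope = c("local", "global")) {
  S <- as.matrix(S)
  scope <- match.arg(scope)
  if (!all(is.finite(S))) stop("profiles contain non-finite entries", call. = FALSE)
  if (is.null(wavelengths)) wavelengths <- seq_len(nrow(S))
  if (length(wavelengths) != nrow(S)) {
    stop("wavelength axis does not match profile length", call. = FALSE)
  }
  structure(list(S = S, wavelengths = as.numeric(wavelengths), scope = scope),
            class = "pure_component_profiles")
}

#' @export
print.pure_component_profiles <- function(x, ...) {
  cat("<pure_component_profiles> ", nrow(x$S), " wavelengths x ", ncol(x$S),
      " components (", x$scope, ")\n", sep = "")
  invisible(x)
}

#' Estimate pure-component profiles by (non-negative) least squares
#'
#' Classical least-squares estimation of per-unit-concentration spectra from
#' samples with known composition: finds `S` minimizing
#' `||X_sub - Y_sub %*% t(S)||_F^2`, solved independently per wavelength
#' (one P-dimensional least-squares problem per column of `X_sub`). The
#' `"nnls"` solver constrains every coefficient to be non-negative; the
#' `"ols"` solver is unconstrained and returns the minimum-norm solution
#' when `Y_sub` is rank deficient (with a warning).
#'
#' @param X_sub absorbance matrix of the subset, n x N.
#' @param Y_sub concentration matrix of the subset, n x P.
#' @param solver `"nnls"` (default) or `"ols"`.
#' @param wavelengths optional axis carried into the result.
#' @param scope profile scope label, default `"local"`.
#' @return A [pure_component_profiles()] with `S` of shape N x P.
#' @export
estimate_pure_components <- function(X_sub, Y_sub,
                                     solver = c("nnls", "ols"),
                                     wavelengths = NULL, scope = "local") {
  solver <- match.arg(solver)
  X_sub <- as.matrix(X_sub)
  Y_sub <- as.matrix(Y_sub)
  if (nrow(X_sub) != nrow(Y_sub)) {
    stop("X_sub and Y_sub row counts differ", call. = FALSE)
  }
  if (nrow(Y_sub) < 1L || ncol(Y_sub) < 1L) {
    stop("subset must contain at least one sample and one component",
         call. = FALSE)
  }
  if (all(Y_sub == 0)) {
    stop("singular subset: all concentrations are zero (",
         nrow(Y_sub), " samples)", call. = FALSE)
  }
  cn <- colnames(Y_sub)
  if (solver == "ols") {
    r <- qr(Y_sub)$rank
    if (r < ncol(Y_sub)) {
      warning("rank-deficient subset (rank ", r, " < ", ncol(Y_sub),
              "); returning the minimum-norm solution", call. = FALSE)
    }
    coef <- pracma::pinv(Y_sub) %*% X_sub        # P x N
  } else {
    coef <- nnls_multi(Y_sub, X_sub)             # P x N
  }
  S <- t(coef)
  colnames(S) <- cn
  pure_component_profiles(S, wavelengths, scope = scope)
}

#' Synthesize a mixture spectrum from pure-component profiles
#'
#' Beer-Lambert mixing: the in-silico spectrum is `S %*% y_star`.
#'
#' @param S a [pure_component_profiles()] or an N x P matrix.
#' @param y_star concentration vector of length P.
#' @return Numeric spectrum of length N.
#' @export
synthesize_spectrum <- function(S, y_star) {
  Sm <- if (inherits(S, "pure_component_profiles")) S$S else as.matrix(S)
  y_star <- as.numeric(y_star)
  if (length(y_star) != ncol(Sm)) {
    stop("y_star length (", length(y_star), ") does not match component count (",
         ncol(Sm), ")", call. = FALSE)
  }
  as.numeric(Sm %*% y_star)
}
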