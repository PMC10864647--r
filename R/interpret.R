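#' Per-wavelength importance result
#'
#' @param method `"gradcam"`, `"shap"`, `"vip"` or `"coefficients"`.
#' @param component component index the attribution refers to.
#' @param values per-wavelength importance vector of length N (for
#'   per-sample methods, the mean over samples).
#' @param wavelengths axis of length N.
#' @param per_sample optional per-sample breakdown (samples x N), for
#'   `shap` and `gradcam`.
#' @param metadata optional list of method details.
#' @return Object of class `importance_result`.
#' @export
importance_result <- function(method, component, values, wavelengths,
                              per_sample = NULL, metadata = list()) {
  method <- match.arg(method, c("gradcam", "shap", "vip", "coefficients"))
  values <- as.numeric(values)
  if (length(values) != length(wavelengths)) {
    stop("importance vector length must equal the wavelength count",
         call. = FALSE)
  }
  if (method %in% c("gradcam", "vip") && any(values < -1e-12)) {
    stop(method, " importance values must be non-negative", call. = FALSE)
  }
  structure(list(method = method, component = component, values = values,
                 wavelengths = as.numeric(wavelengths),
                 per_sample = per_sample, metadata = metadata),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result> method=", x$method, ", component=", x$component,
      ", N=", length(x$values), "\n", sep = "")
  invisible(x)
}

#' Grad-CAM localization map for a CNN prediction
#'
#' Backward gradients of the selected response are taken with respect to
#' the feature maps of the last convolutional layer, averaged over
#' positions to one weight per filter (global average pooling), and the
#' weighted sum of feature maps is rectified. Because pooling layers reduce
#' the feature length, the rectified map is linearly interpolated back to
#' the input resolution.
#'
#' @param model a trained [build_cnn()] model.
#' @param x one spectrum of length N.
#' @param component response index in `1..P`.
#' @param wavelengths optional axis for the result (defaults to feature
#'   index).
#' @return An [importance_result()] of length N with non-negative values.
#' @export
gradcam_map <- function(model, x, component, wavelengths = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (component < 1L || component > model$n_components) {
    stop("component index out of range", call. = FALSE)
  }
  x <- as.numeric(x)
  if (length(x) != model$n_wavelengths) {
    stop("spectrum length mismatch", call. = FALSE)
  }
  fw <- .cnn_forward(model, matrix(x, 1L), train = FALSE)
  d_pred <- matrix(0, 1L, model$n_components)
  d_pred[1L, component] <- 1
  bw <- .cnn_backward(model, fw$caches, d_pred, want_activation_grads = TRUE)
  last_conv <- paste0("conv", model$arch$n_conv_layers)
  conv_idx <- which(vapply(model$layers, function(l) {
    identical(l$name, last_conv)
  }, logical(1)))
  A <- fw$caches[[conv_idx]]$A          # 1 x L_c x F feature maps
  dA <- bw$act_grads[[last_conv]]       # same shape
  L_c <- dim(A)[2]
  alpha <- apply(dA, 3L, mean)          # global average pooling per filter
  map <- pmax(as.numeric(A[1L, , ] %*% alpha), 0)
  N <- model$n_wavelengths
  values <- if (L_c == N) {
    map
  } else {
    stats::approx(seq_len(L_c), map, xout = seq(1, L_c, length.out = N))$y
  }
  if (is.null(wavelengths)) wavelengths <- seq_len(N)
  importance_result("gradcam", component, values, wavelengths,
                    metadata = list(alpha = alpha, feature_length = L_c))
}

#' Permutation Shapley values for any spectral regression model
#'
#' Interventional Shapley-value estimation: for every spectrum to explain,
#' random feature orderings are walked forward (and, antithetically, in
#' reverse order) starting from a background spectrum; each wavelength's
#' attribution is the average marginal change in the model prediction when
#' that wavelength switches from its background value to its actual value.
#' By construction each completed walk's attributions sum exactly to
#' `f(x) - f(background)`, so the averaged rows satisfy
#' `sum(phi) = f(x) - mean(sampled background predictions)`.
#'
#' @param predict_fn function mapping an M x N spectra matrix to
#'   predictions (vector or M x P matrix).
#' @param background non-empty background spectra matrix (masked
#'   wavelengths take values from its rows).
#' @param explain spectra to explain, M_e x N.
#' @param component response column used when `predict_fn` returns a
#'   matrix, default 1.
#' @param n_permutations number of antithetic ordering pairs per spectrum.
#' @param seed optional integer seed.
#' @param chunk_size maximum rows per `predict_fn` call.
#' @return An [importance_result()] with `per_sample` the M_e x N matrix
#'   of Shapley values; `metadata$base_values` holds the per-sample mean
#'   background prediction and `metadata$fx` the model predictions.
#' @export
permutation_shap <- function(predict_fn, background, explain, component = 1L,
                             n_permutations = 10L, seed = NULL,
                             chunk_size = 20000L) {
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  if (is.vector(explain)) explain <- matrix(explain, nrow = 1L)
  background <- as.matrix(background)
  explain <- as.matrix(explain)
  if (nrow(background) < 1L) stop("background set is empty", call. = FALSE)
  if (ncol(background) != ncol(explain)) {
    stop("background/explain wavelength counts differ", call. = FALSE)
  }
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  N <- ncol(explain)
  fcall <- function(X) {
    out <- predict_fn(X)
    if (is.matrix(out)) out[, component] else as.numeric(out)
  }
  .with_seed(seed, {
    phi <- matrix(0, nrow(explain), N)
    base_values <- numeric(nrow(explain))
    fx <- numeric(nrow(explain))
    for (i in seq_len(nrow(explain))) {
      x <- explain[i, ]
      orders <- replicate(n_permutations, sample.int(N), simplify = FALSE)
      bg_rows <- sample.int(nrow(background), n_permutations, replace = TRUE)
      # state matrix for all walks: each walk contributes N + 1 rows
      walks <- vector("list", 2L * n_permutations)
      for (p in seq_len(n_permutations)) {
        walks[[2L * p - 1L]] <- list(o = orders[[p]], bg = bg_rows[p])
        walks[[2L * p]] <- list(o = rev(orders[[p]]), bg = bg_rows[p])
      }
      states <- matrix(0, length(walks) * (N + 1L), N)
      for (w in seq_along(walks)) {
        bg <- background[walks[[w]]$bg, ]
        S <- matrix(bg, N + 1L, N, byrow = TRUE)
        o <- walks[[w]]$o
        for (s in seq_len(N)) S[(s + 1L):(N + 1L), o[s]] <- x[o[s]]
        states[((w - 1L) * (N + 1L) + 1L):(w * (N + 1L)), ] <- S
      }
      preds <- numeric(nrow(states))
      for (s in seq(1L, nrow(states), by = chunk_size)) {
        e <- min(s + chunk_size - 1L, nrow(states))
        preds[s:e] <- fcall(states[s:e, , drop = FALSE])
      }
      contrib <- numeric(N)
      bg_pred_sum <- 0
      for (w in seq_along(walks)) {
        pr <- preds[((w - 1L) * (N + 1L) + 1L):(w * (N + 1L))]
        o <- walks[[w]]$o
        contrib[o] <- contrib[o] + diff(pr)
        bg_pred_sum <- bg_pred_sum + pr[1L]
      }
      phi[i, ] <- contrib / length(walks)
      base_values[i] <- bg_pred_sum / length(walks)
      fx[i] <- preds[N + 1L]
    }
    importance_result("shap", component, colMeans(phi),
                      seq_len(N), per_sample = phi,
                      metadata = list(base_values = base_values, fx = fx,
                                      n_permutations = n_permutations))
  })
}

#' Variable importance in projection (VIP) scores of a PLS1 model
#'
#' For wavelength j, `v_j = sqrt(N * sum_a(ss_a * (w_aj / ||w_a||)^2) /
#' sum_a(ss_a))` with `ss_a = q_a^2 * t_a' t_a` the y-variance explained by
#' component a. The mean of the squared scores equals 1 by construction.
#'
#' @param model a fitted [fit_pls1()] model.
#' @param wavelengths optional axis for the result.
#' @return An [importance_result()] with non-negative values.
#' @export
vip_scores <- function(model, wavelengths = NULL) {
  stopifnot(inherits(model, "pls1_model"))
  W <- model$W
  ss <- model$q^2 * colSums(model$Tt^2)
  Wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  N <- nrow(W)
  v <- sqrt(N * as.numeric(Wn^2 %*% ss) / sum(ss))
  if (is.null(wavelengths)) wavelengths <- seq_len(N)
  importance_result("vip", NA_integer_, v, wavelengths,
                    metadata = list(A = model$A))
}

#' Regression coefficients of a PLS1 model as importance values
#'
#' Returns the regression vector on the preprocessed-spectrum scale; the
#' preprocessing chain (Savitzky-Golay settings and centering constants)
#' is documented in the result metadata.
#'
#' @param model a fitted [fit_pls1()] model.
#' @param wavelengths optional axis for the result.
#' @return An [importance_result()] (values may be negative).
#' @export
pls_coefficients <- function(model, wavelengths = NULL) {
  stopifnot(inherits(model, "pls1_model"))
  if (is.null(wavelengths)) wavelengths <- seq_along(model$beta)
  importance_result("coefficients", NA_integer_, model$beta, wavelengths,
                    metadata = list(A = model$A, sgf = model$sgf,
                                    x_mean = model$x_mean,
                                    y_mean = model$y_mean))
}
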