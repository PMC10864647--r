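# Vectorized forward/backward passes for the small 1-D CNNs.
#
# Activations flow through the network as 3-D arrays (batch, length,
# channels); convolutions are evaluated as a single matrix product after an
# im2col unfold, which keeps the per-batch cost inside BLAS.

.act <- function(z, name) {
  switch(name,
         linear = z,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)))
}

# Derivative of the activation given pre-activation z and activation a.
.dact <- function(z, a, name) {
  switch(name,
         linear = array(1, dim = dim(z)),
         relu = (z > 0) * 1,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a))
}

# Unfold (B, L_in, C) into the (B * L_out) x (width * C) im2col matrix.
# Column (c - 1) * width + k holds positions k .. k + L_out - 1 of channel c.
.im2col <- function(X, width, l_out) {
  B <- dim(X)[1]
  C <- dim(X)[3]
  out <- array(0, dim = c(B, l_out, width * C))
  for (c in seq_len(C)) {
    for (k in seq_len(width)) {
      out[, , (c - 1L) * width + k] <- X[, k:(k + l_out - 1L), c]
    }
  }
  matrix(out, B * l_out, width * C)
}

# Scatter the im2col gradient back onto the input array.
.col2im <- function(dM, B, l_in, C, width, l_out) {
  dX <- array(0, dim = c(B, l_in, C))
  dA <- array(dM, dim = c(B, l_out, width * C))
  for (c in seq_len(C)) {
    for (k in seq_len(width)) {
      rng <- k:(k + l_out - 1L)
      dX[, rng, c] <- dX[, rng, c] + dA[, , (c - 1L) * width + k]
    }
  }
  dX
}

# Forward pass. `train = TRUE` draws dropout masks from the current RNG.
# Returns predictions plus per-layer caches for backprop.
.cnn_forward <- function(model, X, train = FALSE) {
  B <- nrow(X)
  a <- array(X, dim = c(B, ncol(X), 1L))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      Xc <- .im2col(a, ly$width, ly$l_out)
      W <- model$params[[paste0(ly$name, "_W")]]
      b <- model$params[[paste0(ly$name, "_b")]]
      Z <- Xc %*% W
      Z <- sweep(Z, 2L, b, "+")
      Zarr <- array(Z, dim = c(B, ly$l_out, ly$filters))
      Aarr <- .act(Zarr, ly$activation)
      caches[[i]] <- list(Xc = Xc, Z = Zarr, A = Aarr)
      a <- Aarr
    } else if (ly$type == "pool") {
      odd <- 2L * seq_len(ly$l_out) - 1L
      x1 <- a[, odd, , drop = FALSE]
      x2 <- a[, odd + 1L, , drop = FALSE]
      mask1 <- x1 >= x2
      out <- pmax(x1, x2)
      caches[[i]] <- list(mask1 = mask1, l_in = ly$l_in)
      a <- out
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(dims = dim(a))
      a <- matrix(a, B, ly$units)
    } else if (ly$type == "dropout") {
      if (train && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- matrix(stats::rbinom(length(a), 1L, keep) / keep,
                       nrow(a), ncol(a))
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$type == "dense") {
      W <- model$params[[paste0(ly$name, "_W")]]
      b <- model$params[[paste0(ly$name, "_b")]]
      Z <- sweep(a %*% W, 2L, b, "+")
      A <- .act(Z, ly$activation)
      caches[[i]] <- list(X = a, Z = Z, A = A)
      a <- A
    }
  }
  list(pred = a, caches = caches)
}

# Backward pass from an upstream gradient on the predictions. Returns
# parameter gradients and, when `want_activation_grads`, the gradient with
# respect to each conv layer's post-activation output (used by Grad-CAM).
.cnn_backward <- function(model, caches, d_pred,
                          want_activation_grads = FALSE) {
  grads <- list()
  act_grads <- list()
  d <- d_pred
  B <- nrow(d_pred)
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    cache <- caches[[i]]
    if (ly$type == "dense") {
      dZ <- d * .dact(cache$Z, cache$A, ly$activation)
      grads[[paste0(ly$name, "_W")]] <- crossprod(cache$X, dZ)
      grads[[paste0(ly$name, "_b")]] <- colSums(dZ)
      d <- dZ %*% t(model$params[[paste0(ly$name, "_W")]])
    } else if (ly$type == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
    } else if (ly$type == "flatten") {
      d <- array(d, dim = cache$dims)
    } else if (ly$type == "pool") {
      if (want_activation_grads) act_grads[[i]] <- NULL
      dX <- array(0, dim = c(B, cache$l_in, dim(d)[3]))
      odd <- 2L * seq_len(ly$l_out) - 1L
      dX[, odd, ] <- d * cache$mask1
      dX[, odd + 1L, ] <- d * !cache$mask1
      d <- dX
    } else if (ly$type == "conv") {
      if (want_activation_grads) act_grads[[ly$name]] <- d
      dZ <- d * .dact(cache$Z, cache$A, ly$activation)
      dZmat <- matrix(dZ, B * ly$l_out, ly$filters)
      grads[[paste0(ly$name, "_W")]] <- crossprod(cache$Xc, dZmat)
      grads[[paste0(ly$name, "_b")]] <- colSums(dZmat)
      dM <- dZmat %*% t(model$params[[paste0(ly$name, "_W")]])
      d <- .col2im(dM, B, ly$l_in, ly$c_in, ly$width, ly$l_out)
    }
  }
  list(grads = grads, act_grads = act_grads)
}

#' Predict concentrations with a CNN model
#'
#' Forward pass without dropout. Outputs are non-negative by the ReLU
#' output layer.
#'
#' @param model a [build_cnn()] (possibly trained) model.
#' @param X spectra matrix M x N.
#' @return M x P matrix of predicted concentrations.
#' @export
predict_cnn <- function(model, X) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$n_wavelengths) {
    stop("spectrum length ", ncol(X), " does not match model input ",
         model$n_wavelengths, call. = FALSE)
  }
  .cnn_forward(model, X, train = FALSE)$pred
}
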