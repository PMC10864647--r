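#' 1-D CNN architecture description
#'
#' The model family used for spectral concentration regression: 1 to 3
#' convolutional layers (no padding, so the feature length shrinks by
#' `width - 1` per layer), max pooling of width 2 after convolutional
#' layers 1 and 2 only, a flattening step, one fully connected layer,
#' dropout, and a dense output layer with ReLU activation so predicted
#' concentrations are non-negative.
#'
#' @param n_conv_layers number of convolutional layers, 1-3.
#' @param n_filters filters per layer (1-10), recycled to
#'   `n_conv_layers`.
#' @param filter_width odd filter widths `>= 3` per layer, recycled.
#' @param fc_units units of the fully connected layer, 5-100.
#' @param conv_activation activation of the convolutional layers; default
#'   `"linear"` (identity).
#' @param fc_activation activation of the fully connected layer; default
#'   `"tanh"`.
#' @param dropout_rate dropout rate after the fully connected layer, in
#'   `[0, 0.3]`.
#' @param l2_factor L2 regularization factor applied to all trainable
#'   weights, in `[0, 1e-3]`.
#' @param weight_init `"uniform"` (random uniform in \[-0.05, 0.05\]) or
#'   `"glorot_uniform"`.
#' @param pool_width pooling window, fixed default 2.
#' @return Object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(n_conv_layers = 1L, n_filters = 5L,
                             filter_width = 9L, fc_units = 12L,
                             conv_activation = c("linear", "tanh", "relu",
                                                 "sigmoid"),
                             fc_activation = c("tanh", "linear", "relu",
                                               "sigmoid"),
                             dropout_rate = 0, l2_factor = 0,
                             weight_init = c("uniform", "glorot_uniform"),
                             pool_width = 2L) {
  conv_activation <- match.arg(conv_activation)
  fc_activation <- match.arg(fc_activation)
  weight_init <- match.arg(weight_init)
  n_conv_layers <- as.integer(n_conv_layers)
  if (n_conv_layers < 1L || n_conv_layers > 3L) {
    stop("n_conv_layers must be 1, 2 or 3", call. = FALSE)
  }
  n_filters <- rep_len(as.integer(n_filters), n_conv_layers)
  filter_width <- rep_len(as.integer(filter_width), n_conv_layers)
  if (any(n_filters < 1L | n_filters > 10L)) {
    stop("n_filters must be in 1..10", call. = FALSE)
  }
  if (any(filter_width < 3L | filter_width %% 2L == 0L)) {
    stop("filter widths must be odd integers >= 3", call. = FALSE)
  }
  fc_units <- as.integer(fc_units)
  if (fc_units < 5L || fc_units > 100L) {
    stop("fc_units must be in 5..100", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate > 0.3) {
    stop("dropout_rate must be in [0, 0.3]", call. = FALSE)
  }
  if (l2_factor < 0 || l2_factor > 1e-3) {
    stop("l2_factor must be in [0, 1e-3]", call. = FALSE)
  }
  structure(
    list(n_conv_layers = n_conv_layers, n_filters = n_filters,
         filter_width = filter_width, fc_units = fc_units,
         conv_activation = conv_activation, fc_activation = fc_activation,
         dropout_rate = dropout_rate, l2_factor = l2_factor,
         weight_init = weight_init, pool_width = as.integer(pool_width)),
    class = "cnn_architecture"
  )
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat("<cnn_architecture> conv ", x$n_conv_layers, "x[filters ",
      paste(x$n_filters, collapse = ","), "; widths ",
      paste(x$filter_width, collapse = ","), "] -> FC ", x$fc_units,
      " (", x$fc_activation, ") -> ReLU output; dropout ", x$dropout_rate,
      ", l2 ", x$l2_factor, "\n", sep = "")
  invisible(x)
}

#' CNN training protocol configuration
#'
#' Defaults follow the standard protocol: Adam with learning rate 1e-3,
#' batch size 100, at most 100 epochs, early stopping with patience 4 on
#' the validation loss (mean MSE over all responses), best-epoch weights
#' restored.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience consecutive non-improving validation epochs before
#'   stopping; must be smaller than `max_epochs`.
#' @param seed optional integer seed (weight order, shuffling, dropout).
#' @return Object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 100L,
                            max_epochs = 100L, patience = 4L, seed = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!.is_count(batch_size)) stop("batch_size must be a positive integer", call. = FALSE)
  if (!.is_count(max_epochs)) stop("max_epochs must be a positive integer", call. = FALSE)
  if (!.is_count(patience)) stop("patience must be a positive integer", call. = FALSE)
  if (patience >= max_epochs) {
    stop("patience (", patience, ") must be smaller than max_epochs (",
         max_epochs, ")", call. = FALSE)
  }
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "training_config"
  )
}

# Layer plan: sequence of layer descriptors with resolved dimensions.
.cnn_plan <- function(arch, n_wavelengths, n_components) {
  L <- as.integer(n_wavelengths)
  C <- 1L
  layers <- list()
  for (l in seq_len(arch$n_conv_layers)) {
    w <- arch$filter_width[l]
    if (w > L) {
      stop("filter width ", w, " of conv layer ", l,
           " exceeds the current feature length ", L, call. = FALSE)
    }
    L_out <- L - w + 1L
    layers[[length(layers) + 1L]] <- list(
      type = "conv", name = paste0("conv", l), width = w, c_in = C,
      filters = arch$n_filters[l], l_in = L, l_out = L_out,
      activation = arch$conv_activation)
    L <- L_out
    C <- arch$n_filters[l]
    if (l <= 2L) {  # pooling after conv layers 1 and 2 only
      L_out <- L %/% arch$pool_width
      if (L_out < 1L) {
        stop("feature length collapsed to zero after pooling at layer ", l,
             call. = FALSE)
      }
      layers[[length(layers) + 1L]] <- list(
        type = "pool", name = paste0("pool", l), width = arch$pool_width,
        l_in = L, l_out = L_out, channels = C)
      L <- L_out
    }
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten", name = "flatten",
                                        l_in = L, channels = C,
                                        units = L * C)
  layers[[length(layers) + 1L]] <- list(
    type = "dense", name = "fc", units_in = L * C, units = arch$fc_units,
    activation = arch$fc_activation)
  layers[[length(layers) + 1L]] <- list(type = "dropout", name = "dropout",
                                        rate = arch$dropout_rate,
                                        units = arch$fc_units)
  layers[[length(layers) + 1L]] <- list(
    type = "dense", name = "out", units_in = arch$fc_units,
    units = as.integer(n_components), activation = "relu")
  layers
}

#' Build a trainable 1-D CNN
#'
#' Instantiates the architecture for a given input/output dimension and
#' initializes the weights. The returned handle carries the layer plan, all
#' parameters, and the total trainable parameter count.
#'
#' @param arch a [cnn_architecture()].
#' @param n_wavelengths input spectrum length N.
#' @param n_components output dimension P.
#' @param seed optional integer seed for weight initialization.
#' @return Object of class `cnn_model` with elements `arch`, `layers`,
#'   `params`, `n_params`, `n_wavelengths`, `n_components`.
#' @export
build_cnn <- function(arch, n_wavelengths, n_components, seed = NULL) {
  stopifnot(inherits(arch, "cnn_architecture"))
  layers <- .cnn_plan(arch, n_wavelengths, n_components)
  init <- function(n_in, n_out, dims) {
    if (arch$weight_init == "uniform") {
      stats::runif(prod(dims), -0.05, 0.05)
    } else {
      lim <- sqrt(6 / (n_in + n_out))
      stats::runif(prod(dims), -lim, lim)
    }
  }
  params <- .with_seed(seed, {
    p <- list()
    for (ly in layers) {
      if (ly$type == "conv") {
        fan_in <- ly$width * ly$c_in
        p[[paste0(ly$name, "_W")]] <-
          matrix(init(fan_in, ly$filters, c(fan_in, ly$filters)),
                 fan_in, ly$filters)
        p[[paste0(ly$name, "_b")]] <- numeric(ly$filters)
      } else if (ly$type == "dense") {
        p[[paste0(ly$name, "_W")]] <-
          matrix(init(ly$units_in, ly$units, c(ly$units_in, ly$units)),
                 ly$units_in, ly$units)
        # the ReLU output starts marginally positive so its gradient is
        # alive for every unit at the first step
        p[[paste0(ly$name, "_b")]] <-
          rep(if (identical(ly$activation, "relu")) 0.01 else 0, ly$units)
      }
    }
    p
  })
  n_params <- sum(vapply(params, length, integer(1)))
  structure(
    list(arch = arch, layers = layers, params = params, n_params = n_params,
         n_wavelengths = as.integer(n_wavelengths),
         n_components = as.integer(n_components)),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> N=", x$n_wavelengths, " -> P=", x$n_components, ", ",
      x$n_params, " trainable parameters\n", sep = "")
  for (ly in x$layers) {
    cat("  ", format(ly$name, width = 8), ly$type,
        switch(ly$type,
               conv = paste0(" width ", ly$width, ", ", ly$c_in, "->",
                             ly$filters, " ch, L ", ly$l_in, "->", ly$l_out),
               pool = paste0(" L ", ly$l_in, "->", ly$l_out),
               dense = paste0(" ", ly$units_in, "->", ly$units, " (",
                              ly$activation, ")"),
               dropout = paste0(" rate ", ly$rate),
               flatten = paste0(" -> ", ly$units)),
        "\n", sep = "")
  }
  invisible(x)
}
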