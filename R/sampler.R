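#' Fit a per-component concentration sampler
#'
#' Approximates the value distribution of each concentration column
#' independently so that new concentration vectors can be drawn for
#' augmentation. Modes:
#' \describe{
#'   \item{`"kde"`}{univariate Gaussian kernel density estimate per column
#'     with Scott's-rule bandwidth `sd(y) * M^(-1/5)`; sampling draws a data
#'     point and adds Gaussian kernel noise.}
#'   \item{`"uniform"`}{uniform on the observed `[min, max]` per column.}
#'   \item{`"normal"`}{Gaussian with the column's sample mean and SD.}
#' }
#' A zero-variance column under `"kde"`/`"normal"` degenerates to a point
#' mass with a warning.
#'
#' @param Y concentration matrix, M x P.
#' @param mode `"kde"` (default), `"uniform"` or `"normal"`.
#' @return Object of class `concentration_sampler`.
#' @export
fit_sampler <- function(Y, mode = c("kde", "uniform", "normal")) {
  mode <- match.arg(mode)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  M <- nrow(Y)
  if (mode != "uniform" && M < 2L) {
    stop("kde/normal samplers need at least 2 samples", call. = FALSE)
  }
  comps <- lapply(seq_len(ncol(Y)), function(p) {
    y <- Y[, p]
    s <- stats::sd(y)
    if (mode != "uniform" && (!is.finite(s) || s == 0)) {
      warning("zero-variance column ", p, ": sampler degenerates to a point mass",
              call. = FALSE)
      return(list(type = "point", value = y[1]))
    }
    switch(mode,
      kde = list(type = "kde", data = y, bw = s * M^(-1 / 5)),
      uniform = list(type = "uniform", min = min(y), max = max(y)),
      normal = list(type = "normal", mean = mean(y), sd = s)
    )
  })
  structure(list(mode = mode, components = comps,
                 component_names = colnames(Y), n_fit = M),
            class = "concentration_sampler")
}

#' @export
print.concentration_sampler <- function(x, ...) {
  cat("<concentration_sampler> mode=", x$mode, ", P=",
      length(x$components), ", fitted on ", x$n_fit, " samples\n", sep = "")
  invisible(x)
}

#' Draw concentration vectors from a fitted sampler
#'
#' Draws are elementwise non-negative: negative draws are rejected and
#' redrawn up to 100 attempts per element, then clamped to zero.
#'
#' @param sampler a [fit_sampler()] result.
#' @param n number of vectors to draw (n = 0 yields an empty matrix).
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched when a seed is given.
#' @return An n x P matrix of non-negative concentrations.
#' @export
sample_concentrations <- function(sampler, n, seed = NULL) {
  stopifnot(inherits(sampler, "concentration_sampler"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0", call. = FALSE)
  P <- length(sampler$components)
  draw <- function() {
    .with_seed(seed, {
      out <- matrix(0, nrow = n, ncol = P)
      for (p in seq_len(P)) {
        cmp <- sampler$components[[p]]
        y <- .draw_component(cmp, n)
        attempts <- 0L
        while (any(y < 0) && attempts < 100L) {
          bad <- y < 0
          y[bad] <- .draw_component(cmp, sum(bad))
          attempts <- attempts + 1L
        }
        out[, p] <- pmax(y, 0)
      }
      out
    })
  }
  out <- draw()
  colnames(out) <- sampler$component_names
  out
}

.draw_component <- function(cmp, n) {
  if (n == 0L) return(numeric(0))
  switch(cmp$type,
    point = rep(cmp$value, n),
    kde = sample(cmp$data, n, replace = TRUE) + stats::rnorm(n, 0, cmp$bw),
    uniform = stats::runif(n, cmp$min, cmp$max),
    normal = stats::rnorm(n, cmp$mean, cmp$sd)
  )
}
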