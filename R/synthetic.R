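#' Specification for a synthetic chromatography data set
#'
#' Describes a multi-experiment chromatography elution monitored by
#' absorbance spectroscopy: smooth pure-component spectra built from
#' Gaussian absorption bands, Gaussian elution peaks per component and
#' experiment, Beer-Lambert mixing, homoscedastic white noise and an
#' optional linear baseline. The ground truth (pure-component profiles and
#' concentrations) is known exactly, so every downstream stage can be tested
#' against it.
#'
#' @param wavelength_start,wavelength_stop,wavelength_step wavelength grid
#'   (default 240-300 nm at 1 nm, i.e. 61 points, the scale of a protein
#'   UV/Vis chromatography run).
#' @param band_params list with one element per component; each element a
#'   list of numeric triples `c(center, width, height)` describing Gaussian
#'   absorption bands (center/width in wavelength units, height in
#'   absorbance per unit concentration).
#' @param elution_params list with one element per experiment; each element
#'   a list with one numeric triple `c(retention, width, height)` per
#'   component (retention/width in fraction-index units, height in
#'   concentration units).
#' @param n_fractions fractions collected per experiment (samples per
#'   group), scalar or one value per experiment; at least 2.
#' @param noise_sd standard deviation of per-cell Gaussian noise, absorbance
#'   units.
#' @param baseline_slope linear baseline slope (absorbance per wavelength
#'   unit), default 0 (the mixing model is then exactly bilinear).
#' @param component_names optional component labels.
#' @param seed integer seed used by [make_dataset()].
#' @return Object of class `synthetic_spec`.
#' @seealso [ds1_like_spec()] for the default preset.
#' @export
synthetic_spec <- function(wavelength_start = 240, wavelength_stop = 300,
                           wavelength_step = 1, band_params, elution_params,
                           n_fractions = 45, noise_sd = 0.001,
                           baseline_slope = 0, component_names = NULL,
                           seed = 1L) {
  if (wavelength_step <= 0) stop("wavelength_step must be > 0", call. = FALSE)
  wl <- seq(wavelength_start, wavelength_stop, by = wavelength_step)
  if (length(wl) < 2L) stop("wavelength grid has fewer than 2 points", call. = FALSE)
  P <- length(band_params)
  if (P < 1L) stop("at least one component is required", call. = FALSE)
  for (p in seq_len(P)) {
    bands <- band_params[[p]]
    if (length(bands) == 0L) {
      stop("component ", p, " has an empty band list", call. = FALSE)
    }
    for (b in bands) {
      if (length(b) != 3L) stop("bands are (center, width, height) triples", call. = FALSE)
      if (b[2] <= 0) stop("band widths must be > 0", call. = FALSE)
      if (b[3] < 0) stop("band heights must be >= 0", call. = FALSE)
    }
  }
  E <- length(elution_params)
  if (E < 1L) stop("at least one experiment is required", call. = FALSE)
  n_fractions <- rep_len(as.integer(n_fractions), E)
  if (any(n_fractions < 2L)) stop("n_fractions must be >= 2", call. = FALSE)
  for (e in seq_len(E)) {
    peaks <- elution_params[[e]]
    if (length(peaks) != P) {
      stop("experiment ", e, " must list one elution peak per component",
           call. = FALSE)
    }
    for (pk in peaks) {
      if (length(pk) != 3L) stop("peaks are (retention, width, height) triples", call. = FALSE)
      if (pk[2] <= 0) stop("peak widths must be > 0", call. = FALSE)
      if (pk[3] < 0) stop("peak heights must be >= 0", call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(component_names)) component_names <- paste0("comp", seq_len(P))
  structure(
    list(wavelengths = wl, band_params = band_params,
         elution_params = elution_params, n_fractions = n_fractions,
         noise_sd = noise_sd, baseline_slope = baseline_slope,
         component_names = as.character(component_names),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default synthetic preset: three proteins, five elution experiments
#'
#' Emulates the scale of a model-protein chromatography calibration set:
#' three components with overlapping UV absorption bands in 240-300 nm
#' (aromatic ~275-285 nm bands plus a rising short-wavelength edge), five
#' experiments with 45 elution fractions each (225 samples), 61 wavelengths.
#' Retention times drift across experiments so the local composition
#' neighborhoods differ between runs, which is what local subset estimation
#' exploits.
#'
#' @param noise_sd per-cell noise SD (absorbance units), default 0.001.
#' @param n_experiments number of experiments (groups), default 5.
#' @param n_fractions fractions per experiment, default 45.
#' @param baseline_slope linear baseline slope, default 0.
#' @param seed integer seed.
#' @return A [synthetic_spec()].
#' @export
#' @examples
#' sim <- make_dataset(ds1_like_spec(seed = 7))
#' sim$dataset
ds1_like_spec <- function(noise_sd = 0.001, n_experiments = 5,
                          n_fractions = 45, baseline_slope = 0, seed = 1L) {
  bands <- list(
    ribA = list(c(246, 10, 0.9), c(277.5, 7, 0.45)),
    cytC = list(c(249, 9, 1.1), c(264, 8, 0.6), c(290, 9, 0.35)),
    lys  = list(c(251, 11, 0.8), c(281.5, 6.5, 0.85))
  )
  # retention times and peak widths scale with the fraction count so every
  # component elutes inside the collected window
  sc <- n_fractions / 45
  base_ret <- c(14, 22, 30) * sc
  # peaks overlap substantially: fractions are true mixtures, as in the
  # co-eluting protein separations this workflow is meant for
  widths <- c(7, 9, 7.5) * sc
  heights <- c(2.0, 1.5, 2.5)
  elution <- lapply(seq_len(n_experiments), function(e) {
    drift <- (e - (n_experiments + 1) / 2) * 1.6 * sc
    lapply(1:3, function(p) {
      c(base_ret[p] + drift + 0.4 * sc * (p - 2) * (e - 1),
        widths[p] * (1 + 0.06 * (e - 1)),
        heights[p] * (1 + 0.10 * ((e %% 3) - 1)))
    })
  })
  synthetic_spec(band_params = bands, elution_params = elution,
                 n_fractions = n_fractions, noise_sd = noise_sd,
                 baseline_slope = baseline_slope,
                 component_names = names(bands), seed = seed)
}

#' Ground-truth pure-component spectra of a synthetic specification
#'
#' @param spec a [synthetic_spec()].
#' @return A [pure_component_profiles()] object (N x P, scope `"global"`)
#'   whose columns are sums of Gaussian bands on the wavelength grid.
#' @export
make_pure_spectra <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  wl <- spec$wavelengths
  S <- vapply(spec$band_params, function(bands) {
    col <- numeric(length(wl))
    for (b in bands) col <- col + b[3] * exp(-0.5 * ((wl - b[1]) / b[2])^2)
    col
  }, numeric(length(wl)))
  colnames(S) <- spec$component_names
  pure_component_profiles(S, wl, scope = "global")
}

#' Ground-truth concentration profiles of a synthetic specification
#'
#' Each experiment contributes `n_fractions` samples whose component
#' concentrations follow Gaussian elution peaks over the fraction index.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `Y` (M x P concentration matrix) and `groups`
#'   (experiment labels of length M).
#' @export
make_concentration_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  P <- length(spec$band_params)
  blocks <- lapply(seq_along(spec$elution_params), function(e) {
    frac <- seq_len(spec$n_fractions[e])
    Y <- vapply(spec$elution_params[[e]], function(pk) {
      pk[3] * exp(-0.5 * ((frac - pk[1]) / pk[2])^2)
    }, numeric(length(frac)))
    list(Y = Y, groups = rep(paste0("exp", e), length(frac)))
  })
  Y <- do.call(rbind, lapply(blocks, `[[`, "Y"))
  colnames(Y) <- spec$component_names
  list(Y = Y, groups = unlist(lapply(blocks, `[[`, "groups")))
}

#' Generate a synthetic spectral data set with known ground truth
#'
#' Applies the Beer-Lambert bilinear model `X = Y %*% t(S_true)`, adds the
#' optional linear baseline and per-cell Gaussian noise. Reproducible under
#' the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a [spectral_dataset()]) and `S_true` (the
#'   generating [pure_component_profiles()]).
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- make_pure_spectra(spec)
  conc <- make_concentration_profiles(spec)
  X <- conc$Y %*% t(S$S)
  wl <- spec$wavelengths
  if (spec$baseline_slope != 0) {
    X <- X + rep(spec$baseline_slope * (wl - wl[1]), each = nrow(X))
  }
  if (spec$noise_sd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(spec$seed)
    X <- X + matrix(stats::rnorm(length(X), 0, spec$noise_sd), nrow(X))
  }
  ds <- spectral_dataset(X, conc$Y, wl,
                         component_names = spec$component_names,
                         groups = conc$groups)
  list(dataset = ds, S_true = S)
}
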