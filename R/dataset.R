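#' Spectral calibration data set
#'
#' Bundles paired absorbance spectra and reference concentrations with the
#' wavelength axis and per-sample group labels (experiment/run IDs) used for
#' leave-one-group-out cross-validation.
#'
#' @param X numeric matrix, M samples x N wavelengths (absorbance, e.g. mAU).
#' @param Y numeric matrix, M samples x P components (concentration, e.g. g/L).
#'   A vector is treated as a single-component matrix.
#' @param wavelengths strictly increasing numeric axis of length N (nm or
#'   1/cm).
#' @param component_names character vector of P component labels. Defaults to
#'   the column names of `Y` or `comp1..compP`.
#' @param groups vector of M group labels (experiment IDs); coerced to
#'   character.
#' @param sample_ids optional character vector of M unique sample IDs.
#'
#' @return An object of class `spectral_dataset`: a list with elements `X`,
#'   `Y`, `wavelengths`, `component_names`, `groups`, `sample_ids`.
#' @export
#' @examples
#' wl <- 240:245
#' X <- matrix(runif(12), 2, 6)
#' Y <- matrix(c(1, 2), 2, 1)
#' ds <- spectral_dataset(X, Y, wl, "lysozyme", groups = c("e1", "e1"))
#' ds
spectral_dataset <- function(X, Y, wavelengths, component_names = NULL,
                             groups = NULL, sample_ids = NULL) {
  X <- as.matrix(X)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) {
    stop("row counts of X (", nrow(X), ") and Y (", nrow(Y), ") differ",
         call. = FALSE)
  }
  M <- nrow(X)
  N <- ncol(X)
  P <- ncol(Y)
  if (N < 2L) stop("at least 2 wavelengths are required", call. = FALSE)
  if (P < 1L) stop("at least one component is required", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != N) {
    stop("wavelength axis length (", length(wavelengths),
         ") does not match ncol(X) (", N, ")", call. = FALSE)
  }
  if (anyNA(wavelengths) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (is.null(component_names)) {
    component_names <- colnames(Y)
    if (is.null(component_names)) component_names <- paste0("comp", seq_len(P))
  }
  component_names <- as.character(component_names)
  if (length(component_names) != P) {
    stop("component_names must have length ", P, call. = FALSE)
  }
  if (is.null(groups)) groups <- rep("all", M)
  groups <- as.character(groups)
  if (length(groups) != M) {
    stop("groups must have length ", M, call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(M))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (length(sample_ids) != M) stop("sample_ids must have length ", M, call. = FALSE)
  dimnames(X) <- list(sample_ids, NULL)
  dimnames(Y) <- list(sample_ids, component_names)
  structure(
    list(X = X, Y = Y, wavelengths = wavelengths,
         component_names = component_names, groups = groups,
         sample_ids = sample_ids),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset>\n")
  cat("  samples:    ", nrow(x$X), " in ", length(unique(x$groups)),
      " group(s)\n", sep = "")
  cat("  wavelengths:", length(x$wavelengths), " [",
      x$wavelengths[1], "..", x$wavelengths[length(x$wavelengths)], "]\n",
      sep = "")
  cat("  components: ", paste(x$component_names, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) c(nrow(x$X), ncol(x$X), ncol(x$Y))

#' Subset a spectral data set by sample index
#'
#' @param ds a [spectral_dataset()].
#' @param idx integer or logical index over samples.
#' @return A `spectral_dataset` with the selected rows.
#' @export
subset_samples <- function(ds, idx) {
  stopifnot(inherits(ds, "spectral_dataset"))
  spectral_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx, , drop = FALSE],
                   ds$wavelengths, ds$component_names,
                   ds$groups[idx], ds$sample_ids[idx])
}

#' Read a spectral data set from the two-CSV dialect
#'
#' The spectra file holds one row per sample with columns `sample_id`,
#' `group`, then one numeric-named column per wavelength; the concentrations
#' file holds `sample_id` then one column per component. Samples are aligned
#' by ID, so row order may differ between the two files.
#'
#' @param spectra_path path to the spectra CSV.
#' @param concentrations_path path to the concentrations CSV.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(spectra_path, concentrations_path) {
  for (p in c(spectra_path, concentrations_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  sp <- utils::read.csv(spectra_path, check.names = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  co <- utils::read.csv(concentrations_path, check.names = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(sp) < 4L || names(sp)[1] != "sample_id" || names(sp)[2] != "group") {
    stop("spectra file must have columns sample_id, group, then wavelengths: ",
         spectra_path, call. = FALSE)
  }
  if (ncol(co) < 2L || names(co)[1] != "sample_id") {
    stop("concentrations file must have sample_id then component columns: ",
         concentrations_path, call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(names(sp)[-(1:2)]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header in ", spectra_path, call. = FALSE)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelength headers are not strictly increasing in ", spectra_path,
         call. = FALSE)
  }
  ids_sp <- as.character(sp$sample_id)
  ids_co <- as.character(co$sample_id)
  if (anyDuplicated(ids_sp) || anyDuplicated(ids_co)) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  if (!setequal(ids_sp, ids_co)) {
    missing_sp <- setdiff(ids_co, ids_sp)
    missing_co <- setdiff(ids_sp, ids_co)
    stop("sample IDs do not match between files (",
         length(missing_sp) + length(missing_co), " unmatched)",
         call. = FALSE)
  }
  co <- co[match(ids_sp, ids_co), , drop = FALSE]
  X <- as.matrix(sp[, -(1:2), drop = FALSE])
  Y <- as.matrix(co[, -1, drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) {
    stop("non-numeric absorbance values in ", spectra_path, call. = FALSE)
  }
  if (!is.numeric(Y) || anyNA(Y)) {
    stop("non-numeric concentration values in ", concentrations_path,
         call. = FALSE)
  }
  spectral_dataset(X, Y, wl, component_names = names(co)[-1],
                   groups = sp$group, sample_ids = ids_sp)
}

#' Write a spectral data set as the two-CSV dialect
#'
#' Emits `<prefix>_spectra.csv` and `<prefix>_concentrations.csv` in the
#' dialect accepted by [read_dataset()] (comma separated, `.` decimal,
#' UTF-8, mandatory header).
#'
#' @param ds a [spectral_dataset()].
#' @param out_dir output directory; created if missing.
#' @param prefix file-name prefix, default `"dataset"`.
#' @return Invisibly, a named character vector with the two file paths.
#' @export
write_dataset <- function(ds, out_dir, prefix = "dataset") {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (ncol(ds$Y) < 1L) stop("data set has no components", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sp_path <- file.path(out_dir, paste0(prefix, "_spectra.csv"))
  co_path <- file.path(out_dir, paste0(prefix, "_concentrations.csv"))
  sp <- data.frame(sample_id = ds$sample_ids, group = ds$groups,
                   check.names = FALSE, stringsAsFactors = FALSE)
  Xdf <- as.data.frame(ds$X)
  names(Xdf) <- format(ds$wavelengths, trim = TRUE, digits = 15)
  sp <- cbind(sp, Xdf)
  co <- data.frame(sample_id = ds$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  Ydf <- as.data.frame(ds$Y)
  names(Ydf) <- ds$component_names
  co <- cbind(co, Ydf)
  for (attempt in list(list(df = sp, path = sp_path),
                       list(df = co, path = co_path))) {
    ok <- tryCatch({
      utils::write.csv(attempt$df, attempt$path, row.names = FALSE,
                       fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("failed to write ", attempt$path, ": ", conditionMessage(ok),
           call. = FALSE)
    }
  }
  invisible(c(spectra = sp_path, concentrations = co_path))
}
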