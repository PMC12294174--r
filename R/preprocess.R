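#' Spectral preprocessing operators
#'
#' Three classical, row-independent operators, applied as alternatives
#' (never chained): linear baseline correction anchored at the first and
#' last band, multiplicative scatter correction (MSC) against a reference
#' spectrum, and the Savitzky-Golay first derivative (SG1st). All are
#' deterministic.
#'
#' `baseline_correct()` subtracts from each spectrum the straight line
#' through its endpoints (the 400 and 1000 nm grid ends), making a tilted
#' baseline horizontal; corrected endpoints are exactly zero.
#'
#' @param spectra numeric matrix (samples x bands) or a single spectrum.
#' @param wavelengths nm vector matching the band count.
#' @return A matrix (or vector) of the same shape.
#' @export
baseline_correct <- function(spectra, wavelengths) {
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, 1) else as.matrix(spectra)
  p <- ncol(X)
  if (p < 2) abort("need at least 2 bands")
  if (length(wavelengths) != p) abort("wavelength/band count mismatch")
  frac <- (wavelengths - wavelengths[1]) / (wavelengths[p] - wavelengths[1])
  chord <- outer(X[, 1], 1 - frac) + outer(X[, p], frac)
  out <- X - chord
  if (vec) drop(out) else out
}

#' @rdname baseline_correct
#'
#' @details
#' `msc()` regresses each spectrum on the reference,
#' `x ~ a + b * reference`, and returns `(x - a) / b`, removing additive
#' offset and multiplicative scatter gain. The reference is typically the
#' calibration-set mean spectrum and must be estimated from calibration
#' rows only. Rows with `|b|` below `tol` are passed through unchanged
#' with a warning.
#'
#' @param reference reference spectrum (length = band count), non-constant.
#' @param tol slope magnitude below which a row is left uncorrected.
#' @export
msc <- function(spectra, reference, tol = 1e-10) {
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, 1) else as.matrix(spectra)
  if (length(reference) != ncol(X)) abort("reference/band count mismatch")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) abort("`reference` must be non-constant")
  b <- as.vector(X %*% rc) / denom
  a <- rowMeans(X) - b * mean(reference)
  degenerate <- abs(b) < tol
  if (any(degenerate)) {
    warn(sprintf("%d spectra with near-zero MSC slope passed through",
                 sum(degenerate)))
    b[degenerate] <- 1
    a[degenerate] <- 0
  }
  out <- (X - a) / b
  if (vec) drop(out) else out
}

#' @rdname baseline_correct
#'
#' @details
#' `sg1st()` applies a Savitzky-Golay first-derivative filter: a local
#' polynomial of order `polyorder` is fitted in a moving window of
#' `window` bands and its analytic first derivative replaces each point.
#' Derivatives are per nm (the filter is scaled by the band spacing;
#' the grid is assumed uniform). Edges are handled by evaluating the
#' polynomial fit of the first/last full window at the edge points, so
#' polynomials up to `polyorder` are differentiated exactly everywhere.
#'
#' @param window odd filter length in bands (default 5).
#' @param polyorder polynomial order, >= 1 and < `window` (default 2).
#' @export
sg1st <- function(spectra, wavelengths, window = 5, polyorder = 2) {
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, 1) else as.matrix(spectra)
  window <- check_count(window, "window", min = 3L)
  polyorder <- check_count(polyorder, "polyorder", min = 1L)
  if (window %% 2 == 0) abort("`window` must be odd")
  if (polyorder >= window) abort("`polyorder` must be < `window`")
  if (ncol(X) < window) abort("need at least `window` bands")
  if (length(wavelengths) != ncol(X)) abort("wavelength/band count mismatch")
  spacing <- mean(diff(wavelengths))
  out <- t(apply(X, 1, signal::sgolayfilt,
                 p = polyorder, n = window, m = 1, ts = spacing))
  if (vec) drop(out) else out
}

#' Band-wise standardization (autoscaling)
#'
#' Centers and scales every band to unit variance and divides by the
#' square root of the band count, so the expected squared distance
#' between two unrelated samples is ~2 regardless of the preprocessing
#' applied. This makes one `(C, g)` search box usable across raw,
#' baseline, MSC and derivative features, whose native scales differ by
#' orders of magnitude. Statistics default to those of `X` itself; pass
#' the calibration-set statistics when transforming prediction rows.
#'
#' @param X numeric matrix, samples x bands.
#' @param stats optional statistics from a previous call (its `stats`
#'   attribute), to reuse calibration centers/scales.
#' @return The standardized matrix with a `stats` attribute
#'   (`list(center, scale)`).
#' @export
standardize_bands <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
    stats <- list(center = colMeans(X), scale = sdev * sqrt(ncol(X)))
  }
  out <- sweep(sweep(X, 2, stats$center), 2, stats$scale, "/")
  attr(out, "stats") <- stats
  out
}

#' Apply a preprocessing method to a spectra table
#'
#' Tidy front end over the operator functions: takes and returns a
#' spectra table. For `"msc"`, the reference defaults to the mean spectrum
#' of the table itself; pass the calibration-set mean explicitly when
#' transforming prediction rows, so no statistic leaks across the split.
#'
#' @param table a spectra table.
#' @param method one of `"none"`, `"baseline"`, `"msc"`, `"sg1st"`.
#' @param reference MSC reference spectrum (default: column means of
#'   `table`).
#' @param window,polyorder SG1st filter settings.
#' @return The transformed spectra table.
#' @export
preprocess_spectra <- function(table,
                               method = c("none", "baseline", "msc", "sg1st"),
                               reference = NULL, window = 5, polyorder = 2) {
  method <- match.arg(method)
  if (method == "none") return(table)
  X <- spectra_matrix(table)
  w <- spectra_wavelengths(table)
  out <- switch(method,
    baseline = baseline_correct(X, w),
    msc = msc(X, reference %||% colMeans(X)),
    sg1st = sg1st(X, w, window = window, polyorder = polyorder)
  )
  set_spectra_matrix(table, out)
}
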