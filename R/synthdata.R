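#' Configuration for the synthetic spectra generator
#'
#' Defines the study conditions emulated by [generate_spectra()]: 15 dried
#' jujube varieties, 180 fruit per variety, 229 bands spanning 400-1000 nm.
#' Each variety has a smooth reflectance template — a sigmoid rising through
#' the visible/NIR transition, minus Gaussian chlorophyll absorption dips
#' near 650 and 670 nm and water absorption dips near 920 and 970 nm, plus
#' a broad water-related bump near 870 nm. Varieties differ by small
#' wavelength shifts of these features (`class_peak_shifts`), by
#' deterministic per-variety feature-depth modulation, and by slight
#' baseline differences. Individual fruit deviate from their template by
#' a multiplicative scatter gain, an additive offset, a random linear
#' baseline tilt, and i.i.d. band noise. The default noise budget makes
#' the raw spectra hardest to classify (scatter, offset and tilt dominate
#' the between-variety signal) while scatter-correcting or derivative
#' preprocessing recovers the variety differences — the difficulty
#' ordering typical of dried-fruit visible/NIR studies.
#'
#' @param n_classes number of varieties (default 15).
#' @param n_per_class samples per variety (default 180).
#' @param n_bands number of spectral bands (default 229, must be >= 5).
#' @param wavelength_range length-2 nm range of the grid (default 400-1000).
#' @param class_peak_shifts per-class nm offsets applied to all absorption
#'   features; default evenly spaced over \[-7, 7\] nm.
#' @param scatter_sd sd of the multiplicative gain around 1 (default 0.10).
#' @param offset_sd sd of the additive reflectance offset (default 0.02).
#' @param tilt_sd sd of the random linear baseline tilt, expressed as the
#'   reflectance change across the full wavelength range (default 0.03).
#' @param noise_sd sd of i.i.d. per-band noise in reflectance units
#'   (default 0.0015); mean-ROI spectra are smooth, so this is small.
#' @param outlier_fraction proportion of samples later replaced by gross
#'   outliers, in \[0, 0.5) (default 0.05).
#' @param seed integer RNG seed; every generator call is deterministic
#'   given the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 15, n_per_class = 180, n_bands = 229,
                         wavelength_range = c(400, 1000),
                         class_peak_shifts = NULL,
                         scatter_sd = 0.10, offset_sd = 0.02,
                         tilt_sd = 0.03, noise_sd = 0.0015,
                         outlier_fraction = 0.05, seed = 1L) {
  n_classes <- check_count(n_classes, "n_classes")
  n_per_class <- check_count(n_per_class, "n_per_class")
  n_bands <- check_count(n_bands, "n_bands", min = 5L)
  if (length(wavelength_range) != 2 || diff(wavelength_range) <= 0) {
    abort("`wavelength_range` must be an increasing nm pair")
  }
  if (is.null(class_peak_shifts)) {
    class_peak_shifts <- if (n_classes == 1) 0 else
      seq(-7, 7, length.out = n_classes)
  }
  if (length(class_peak_shifts) != n_classes) {
    abort("`class_peak_shifts` must have one entry per class")
  }
  check_proportion(outlier_fraction, "outlier_fraction", 0, 0.5,
                   hi_open = TRUE)
  if (scatter_sd < 0 || offset_sd < 0 || noise_sd < 0 || tilt_sd < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(list(
    n_classes = n_classes, n_per_class = n_per_class, n_bands = n_bands,
    wavelength_range = wavelength_range,
    class_peak_shifts = class_peak_shifts,
    scatter_sd = scatter_sd, offset_sd = offset_sd, tilt_sd = tilt_sd,
    noise_sd = noise_sd,
    outlier_fraction = outlier_fraction, seed = as.integer(seed)
  ), class = "synth_config")
}

# absorption features of the dried-fruit reflectance template:
# chlorophyll dips at 650/670 nm, water dips at 920/970 nm, water bump 870 nm
template_features <- function() {
  tibble::tibble(
    center = c(650, 670, 870, 920, 970),
    depth  = c(0.030, 0.025, -0.025, 0.030, 0.050),
    width  = c(12, 10, 35, 22, 28),
    phase  = c(0, 1.3, 2.6, 3.9, 5.2)
  )
}

#' Per-class reflectance templates
#'
#' @param config a [synth_config()].
#' @return A `n_classes` x `n_bands` matrix of noise-free class templates,
#'   with class labels as row names and a `wavelengths` attribute.
#' @export
class_templates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  w <- seq(config$wavelength_range[1], config$wavelength_range[2],
           length.out = config$n_bands)
  K <- config$n_classes
  feats <- template_features()
  out <- matrix(0, K, config$n_bands,
                dimnames = list(sprintf("class%02d", seq_len(K)), NULL))
  for (k in seq_len(K)) {
    u <- (k - 1) / K
    mid <- 620 + 3 * cos(2 * pi * u)          # per-class sigmoid midpoint
    amp <- 0.72 + 0.01 * sin(4 * pi * u + 1)  # per-class NIR plateau
    base <- 0.12 + (amp - 0.12) / (1 + exp(-(w - mid) / 70))
    for (j in seq_len(nrow(feats))) {
      c_j <- feats$center[j] + config$class_peak_shifts[k]
      d_j <- feats$depth[j] * (1 + 0.25 * sin(2 * pi * u + feats$phase[j]))
      base <- base - d_j * exp(-(w - c_j)^2 / (2 * feats$width[j]^2))
    }
    out[k, ] <- base
  }
  attr(out, "wavelengths") <- w
  out
}

#' Generate a synthetic spectra table
#'
#' Draws `n_classes * n_per_class` reflectance spectra: each sample is
#' `gain * template + offset + tilt + noise` with
#' `gain ~ N(1, scatter_sd)`, `offset ~ N(0, offset_sd)`, a linear tilt
#' of `N(0, tilt_sd)` reflectance across the wavelength range, and
#' i.i.d. `N(0, noise_sd)` band noise. Deterministic given
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return A [spectra_tbl()] with `n_classes * n_per_class` rows and a
#'   `.outlier_truth` column (all `FALSE`; see [inject_outliers()]).
#' @export
generate_spectra <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  tmpl <- class_templates(config)
  w <- attr(tmpl, "wavelengths")
  n <- config$n_classes * config$n_per_class
  labels <- rep(rownames(tmpl), each = config$n_per_class)
  X <- withr::with_seed(config$seed, {
    gain <- rnorm(n, 1, config$scatter_sd)
    offset <- rnorm(n, 0, config$offset_sd)
    tilt <- rnorm(n, 0, config$tilt_sd)
    ramp <- (w - w[1]) / (w[length(w)] - w[1]) - 0.5
    noise <- matrix(rnorm(n * config$n_bands, 0, config$noise_sd),
                    n, config$n_bands)
    tmpl[rep(seq_len(config$n_classes), each = config$n_per_class), ,
         drop = FALSE] * gain + offset + outer(tilt, ramp) + noise
  })
  spectra_tbl(X, w, labels, outlier_truth = rep(FALSE, n))
}

#' Replace a fraction of samples with gross spectral outliers
#'
#' Emulates acquisition failures: each corrupted sample receives one of a
#' large additive offset, a large multiplicative gain error, or heavy
#' spike noise, of size `magnitude` (reflectance units) — far beyond the
#' generator's nominal noise. Exactly `floor(fraction * n)` rows are
#' corrupted; the remaining rows are untouched.
#'
#' @param table a spectra table.
#' @param fraction proportion of rows to corrupt, in \[0, 0.5).
#' @param magnitude distortion scale in reflectance units (default 0.3).
#' @param seed integer RNG seed.
#' @return The table with corrupted rows and `.outlier_truth` set.
#' @export
inject_outliers <- function(table, fraction = 0.05, magnitude = 0.3,
                            seed = 1L) {
  check_proportion(fraction, "fraction", 0, 0.5, hi_open = TRUE)
  n <- nrow(table)
  k <- floor(fraction * n)
  table$.outlier_truth <- rep(FALSE, n)
  if (k == 0) return(table)
  X <- spectra_matrix(table)
  withr::with_seed(seed, {
    rows <- sample(n, k)
    kind <- sample(c("offset", "gain", "spike"), k, replace = TRUE)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    for (i in seq_len(k)) {
      r <- rows[i]
      X[r, ] <- switch(kind[i],
        offset = X[r, ] + sgn[i] * magnitude,
        gain   = X[r, ] * (1 + sgn[i] * 2 * magnitude),
        spike  = X[r, ] + rnorm(ncol(X), 0, magnitude)
      )
    }
  })
  table <- set_spectra_matrix(table, X)
  table$.outlier_truth[rows] <- TRUE
  table
}
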