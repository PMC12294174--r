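#' Hyperspectral cubes and calibration frames
#'
#' A hypercube is a `rows x cols x bands` numeric array with a
#' `wavelengths` attribute (nm). Calibration frames bundle the raw cube
#' with white- and dark-reference acquisitions; the references may be full
#' cubes or single `cols x bands` frames, which are broadcast across rows
#' as in line-scan acquisition.
#'
#' @param values `rows x cols x bands` numeric array.
#' @param wavelengths nm vector, one entry per band.
#' @return `hypercube()` returns an object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths) {
  values <- as.array(values)
  if (length(dim(values)) != 3) abort("`values` must be a 3-D array")
  if (dim(values)[3] != length(wavelengths)) {
    abort("`wavelengths` length must equal the band count")
  }
  if (!all(is.finite(values))) abort("cube values must be finite")
  structure(values, wavelengths = as.numeric(wavelengths),
            class = "hypercube")
}

#' @rdname hypercube
#' @param raw,white,dark raw and reference acquisitions (counts); `white`
#'   and `dark` may be cubes matching `raw` or `cols x bands` matrices.
#' @export
calibration_frames <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"))
  structure(list(raw = raw, white = white, dark = dark),
            class = "calibration_frames")
}

# broadcast a reference (cube or cols x bands frame) to raw's dimensions
broadcast_ref <- function(ref, dims) {
  if (length(dim(ref)) == 3) {
    if (!identical(dim(ref)[1:3], dims)) abort("reference cube dims differ")
    unclass(ref)
  } else if (length(dim(ref)) == 2) {
    if (!identical(dim(ref), dims[2:3])) {
      abort("reference frame must be cols x bands")
    }
    aperm(array(rep(ref, each = dims[1]), dims), c(1, 2, 3))
  } else {
    abort("reference must be a cube or a cols x bands matrix")
  }
}

#' Reflectance calibration against white and dark references
#'
#' Converts raw counts to relative reflectance via
#' `R = (raw - dark) / (white - dark)`, elementwise. The white-dark
#' denominator must be non-zero everywhere; values outside \[0, 1\] are
#' passed through with a warning (no clipping).
#'
#' @param frames a [calibration_frames()] object.
#' @return A [hypercube()] of relative reflectance.
#' @export
calibrate_reflectance <- function(frames) {
  stopifnot(inherits(frames, "calibration_frames"))
  raw <- unclass(frames$raw)
  dims <- dim(raw)
  white <- broadcast_ref(frames$white, dims)
  dark <- broadcast_ref(frames$dark, dims)
  denom <- white - dark
  bad <- which(denom == 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dims)
    abort(sprintf(
      "white - dark is zero at pixel (%d, %d), band %d: cannot calibrate",
      idx[1], idx[2], idx[3]))
  }
  R <- (raw - dark) / denom
  if (any(R < 0) || any(R > 1)) {
    warn("calibrated reflectance outside [0, 1]; values passed through")
  }
  hypercube(R, attr(frames$raw, "wavelengths"))
}

#' Threshold segmentation of the sample foreground
#'
#' Reduces the cube to a grayscale image (per-pixel mean over bands, or a
#' single band), thresholds it, and optionally keeps only the largest
#' 4-connected foreground component.
#'
#' @param cube a [hypercube()].
#' @param threshold grayscale intensity cutoff; pixels strictly above it
#'   are foreground.
#' @param band_for_gray `"mean"` (default) or a band index.
#' @param keep_largest keep only the largest connected component
#'   (default `TRUE`).
#' @return A logical `rows x cols` mask.
#' @export
segment_foreground <- function(cube, threshold, band_for_gray = "mean",
                               keep_largest = TRUE) {
  stopifnot(inherits(cube, "hypercube"))
  v <- unclass(cube)
  gray <- if (identical(band_for_gray, "mean")) {
    apply(v, c(1, 2), mean)
  } else {
    v[, , check_count(band_for_gray, "band_for_gray")]
  }
  mask <- gray > threshold
  if (!any(mask)) abort("empty foreground: threshold above every pixel")
  if (keep_largest) mask <- largest_component(mask)
  mask
}

# largest 4-connected component of a small logical mask (flood fill)
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    nr <- nrow(mask)
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                  if (c > 1) p - nr, if (c < ncol(mask)) p + nr)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}

#' Mean spectrum over a region of interest
#'
#' @param cube a [hypercube()].
#' @param mask logical `rows x cols` mask with at least one `TRUE` pixel.
#' @return A numeric vector, the per-band arithmetic mean over masked
#'   pixels, with the cube's wavelengths as names.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (!any(mask)) abort("mask selects no pixels")
  v <- unclass(cube)
  out <- vapply(seq_len(dim(v)[3]),
                function(b) mean(v[, , b][mask]), numeric(1))
  names(out) <- band_names(attr(cube, "wavelengths"))
  out
}

#' Generate a synthetic calibration scene
#'
#' Builds raw, white and dark frames for a small scene in which a disk of
#' foreground pixels carries a known reflectance spectrum (the first class
#' template of `config`), encoded as `raw = R * (white - dark) + dark` so
#' that [calibrate_reflectance()] recovers it exactly. Background pixels
#' encode near-zero reflectance. White counts are ~3500, dark ~90, with
#' small per-pixel variation.
#'
#' @param config a [synth_config()]; only the spectral grid and first
#'   class template are used.
#' @param scene_dim rows/cols of the (square) scene, <= 64 (default 48).
#' @param seed integer RNG seed.
#' @return A list with elements `frames` (a [calibration_frames()]),
#'   `truth_mask` (logical matrix), and `reflectance` (the encoded
#'   foreground spectrum).
#' @export
generate_cube_scene <- function(config = synth_config(), scene_dim = 48,
                                seed = config$seed) {
  scene_dim <- check_count(scene_dim, "scene_dim", min = 8L)
  if (scene_dim > 64) abort("`scene_dim` must be <= 64")
  tmpl <- class_templates(config)
  w <- attr(tmpl, "wavelengths")
  spec <- tmpl[1, ]
  p <- length(w)
  ctr <- (scene_dim + 1) / 2
  d2 <- outer((seq_len(scene_dim) - ctr)^2, (seq_len(scene_dim) - ctr)^2, "+")
  truth <- d2 <= (0.3 * scene_dim)^2
  withr::with_seed(seed, {
    white <- array(rnorm(scene_dim^2 * p, 3500, 20), c(scene_dim, scene_dim, p))
    dark <- array(rnorm(scene_dim^2 * p, 90, 5), c(scene_dim, scene_dim, p))
    Rtruth <- array(rep(0.02, scene_dim^2 * p), c(scene_dim, scene_dim, p))
    for (b in seq_len(p)) {
      plane <- Rtruth[, , b]
      plane[truth] <- spec[b]
      Rtruth[, , b] <- plane
    }
  })
  raw <- Rtruth * (white - dark) + dark
  list(
    frames = calibration_frames(hypercube(raw, w),
                                hypercube(white, w), hypercube(dark, w)),
    truth_mask = truth,
    reflectance = spec
  )
}
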