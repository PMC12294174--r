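#' Exponentially decreasing retention schedule (EDF)
#'
#' CARS forces the retained-band count down an exponential curve
#' `r_i = a * exp(-k * i)` whose constants are fixed by the boundary
#' conditions `ceiling(r_1 * p) = p` (all bands at the first sampling run)
#' and `ceiling(r_N * p) = 2` (two bands at the last), giving
#' `k = log(p / 2) / (N - 1)` and `a = (p / 2)^(1 / (N - 1))`.
#'
#' @param i sampling run index, 1..`n_mc`.
#' @param n_mc total number of Monte Carlo sampling runs.
#' @param p total number of bands (>= 2).
#' @return `edf_ratio()` returns the retention ratio `r_i`;
#'   `edf_retained()` returns the retained count `ceiling(p * r_i)`.
#' @export
edf_ratio <- function(i, n_mc, p) {
  p <- check_count(p, "p", min = 2L)
  n_mc <- check_count(n_mc, "n_mc", min = 2L)
  if (any(i < 1 | i > n_mc)) abort("`i` must lie in 1..n_mc")
  k <- log(p / 2) / (n_mc - 1)
  a <- (p / 2)^(1 / (n_mc - 1))
  a * exp(-k * i)
}

#' @rdname edf_ratio
#' @export
edf_retained <- function(i, n_mc, p) {
  # tolerance guards the exact boundary counts against FP round-up
  pmin(p, pmax(2L, as.integer(ceiling(p * edf_ratio(i, n_mc, p) - 1e-9))))
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Each sampling run draws a Monte Carlo row subset (`mc_fraction` of the
#' samples), fits a PLS model on the currently retained bands, and scores
#' every retained band by the norm of its regression-coefficient row
#' across responses. The exponentially decreasing schedule
#' ([edf_retained()]) fixes how many bands survive the run; which bands
#' survive is decided competitively by a weighted draw without
#' replacement with probabilities proportional to the coefficient
#' magnitudes. The retained set of every run is scored by 10-fold RMSECV
#' on the full sample set, and the set with minimal RMSECV is selected.
#'
#' Class labels are one-hot encoded into a multi-response PLS (PLS2)
#' problem, with RMSECV pooled over response columns.
#'
#' @param X numeric matrix, samples x bands (calibration rows only).
#' @param y class labels (coerced to one-hot responses) or a numeric
#'   response vector/matrix.
#' @param n_mc number of Monte Carlo sampling runs (default 500).
#' @param folds RMSECV folds (default 10).
#' @param max_ncomp maximum PLS components (default
#'   `min(15, ncol(X), nrow(X) - 1)`).
#' @param mc_fraction row fraction drawn per run (default 0.8).
#' @param seed integer RNG seed.
#' @return An object of class `cars_result`: `retained_sets` (per-run
#'   band-index sets), `rmsecv_trace`, `n_retained`, `best_iteration`,
#'   `selected` (band indices at minimal RMSECV), `selected_fraction`
#'   (percent of all bands), and bookkeeping fields.
#' @export
cars_select <- function(X, y, n_mc = 500, folds = 10, max_ncomp = NULL,
                        mc_fraction = 0.8, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) abort("need at least 2 bands")
  n_mc <- check_count(n_mc, "n_mc", min = 2L)
  Y <- if (is.numeric(y)) as.matrix(y) else one_hot(y)
  if (!is.numeric(y) && ncol(Y) < 2) abort("need at least 2 classes")
  max_ncomp <- max_ncomp %||% min(15L, p, n - 1L)
  schedule <- edf_retained(seq_len(n_mc), n_mc, p)
  fold_id <- stratified_folds(if (is.numeric(y)) rep(1, n) else y,
                              folds, seed)
  retained <- seq_len(p)
  retained_sets <- vector("list", n_mc)
  trace <- numeric(n_mc)
  best_ncomps <- integer(n_mc)
  withr::with_seed(seed + 1L, {
    for (i in seq_len(n_mc)) {
      rows <- sample(n, max(2L, round(mc_fraction * n)))
      A <- min(max_ncomp, length(retained), length(rows) - 1L)
      fit <- pls_fit(X[rows, retained, drop = FALSE],
                     Y[rows, , drop = FALSE], A)
      wgt <- sqrt(rowSums(fit$coefficients^2))
      # keep every weight strictly positive so the draw stays feasible
      wgt <- wgt + if (any(wgt > 0)) max(wgt) * 1e-9 else 1
      keep <- min(schedule[i], length(retained))
      retained <- sort(retained[sample.int(length(retained), keep,
                                           prob = wgt)])
      if (length(retained) < 2) break
      cv <- rmsecv(X[, retained, drop = FALSE], Y,
                   min(max_ncomp, length(retained)),
                   folds = folds, fold_id = fold_id)
      retained_sets[[i]] <- retained
      trace[i] <- cv$rmsecv
      best_ncomps[i] <- cv$best_ncomp
    }
  })
  done <- which(!vapply(retained_sets, is.null, logical(1)))
  retained_sets <- retained_sets[done]
  trace <- trace[done]
  best_it <- which.min(trace)
  selected <- retained_sets[[best_it]]
  structure(list(
    retained_sets = retained_sets,
    rmsecv_trace = trace,
    n_retained = lengths(retained_sets),
    best_ncomp_trace = best_ncomps[done],
    best_iteration = best_it,
    selected = selected,
    selected_fraction = selection_percentage(length(selected), p),
    n_mc = n_mc, n_bands = p, seed = as.integer(seed)
  ), class = "cars_result")
}

#' Share of bands kept by a selection, in percent
#'
#' @param n_selected number of selected bands.
#' @param n_bands total number of bands.
#' @return `100 * n_selected / n_bands`.
#' @export
selection_percentage <- function(n_selected, n_bands) {
  100 * n_selected / n_bands
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf(
    "CARS: %d of %d bands selected (%.2f%%) at run %d of %d (RMSECV %.4f)\n",
    length(x$selected), x$n_bands, x$selected_fraction,
    x$best_iteration, length(x$rmsecv_trace), min(x$rmsecv_trace)))
  invisible(x)
}
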