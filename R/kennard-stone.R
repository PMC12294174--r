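#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min-distance sample selection, run within each class
#' so every variety appears in both sets. Per class the first two
#' calibration samples are the pair at maximal Euclidean distance; each
#' further sample maximizes its minimal distance to the already selected
#' set, until `ceiling(ratio * n_class)` are selected. Ties are broken by
#' lowest row index.
#'
#' @param table a spectra table, or a numeric matrix (then supply
#'   `labels`).
#' @param labels class labels (taken from `table$label` for spectra
#'   tables).
#' @param ratio calibration share (default 0.75, i.e. a 3:1 split).
#' @return An object of class `ks_split`: integer row indices
#'   `calibration` and `prediction` (each in increasing order), and the
#'   ratio used.
#' @references Kennard and Stone (1969), Computer aided design of
#'   experiments. Technometrics 11, 137-148.
#' @export
kennard_stone_split <- function(table, labels = NULL, ratio = 0.75) {
  X <- if (inherits(table, "spectra_tbl")) spectra_matrix(table)
       else as.matrix(table)
  labels <- labels %||% table$label
  check_proportion(ratio, "ratio", 0, 1)
  cal <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_cl <- length(idx)
    if (n_cl < 4) abort(sprintf("class '%s' has fewer than 4 samples", cl))
    n_sel <- ceiling(ratio * n_cl)
    D <- sq_dist(X[idx, , drop = FALSE])
    sel <- ks_maxmin(D, n_sel)
    cal <- c(cal, idx[sel])
  }
  cal <- sort(cal)
  structure(list(calibration = cal,
                 prediction = setdiff(seq_along(labels), cal),
                 ratio = ratio), class = "ks_split")
}

# classic Kennard-Stone max-min trace on a squared-distance matrix;
# ties broken by lowest index
ks_maxmin <- function(D, n_sel) {
  n <- nrow(D)
  if (n_sel >= n) return(seq_len(n))
  start <- which(D == max(D), arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE]
  sel <- sort(unname(start[1, ]))
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_sel) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)   # which.max takes the first (lowest-index) tie
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d calibration / %d prediction (ratio %.2f)\n",
              length(x$calibration), length(x$prediction), x$ratio))
  invisible(x)
}
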