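#' Isolation Forest anomaly screening
#'
#' An isolation forest isolates samples by recursive random axis-aligned
#' splits; anomalous samples sit on short paths. Each of `n_trees` trees is
#' grown on an independent random subsample of `subsample_size` rows, with
#' uniformly chosen split attribute and split point, to a depth cap of
#' `ceiling(log2(subsample_size))`. The anomaly score of a sample is
#' `s(x) = 2^(-E[h(x)] / c(psi))` where `E[h(x)]` averages the path length
#' over trees (truncated leaves are credited `c(leaf size)` extra depth)
#' and `c(.)` is the average unsuccessful-search path length of a binary
#' search tree.
#'
#' @param X numeric matrix, samples x features.
#' @param n_trees number of isolation trees (default 100).
#' @param subsample_size rows per tree (default `min(256, nrow(X))`).
#' @param seed integer RNG seed.
#' @return `fit_isolation_forest()` returns an `isolation_forest` model.
#' @references Liu, Ting and Zhou (2008), Isolation Forest, ICDM.
#' @export
fit_isolation_forest <- function(X, n_trees = 100,
                                 subsample_size = min(256, nrow(X)),
                                 seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("need at least 2 samples")
  n_trees <- check_count(n_trees, "n_trees")
  subsample_size <- check_count(subsample_size, "subsample_size", min = 2L)
  if (subsample_size > nrow(X)) abort("`subsample_size` must be <= n")
  max_depth <- ceiling(log2(subsample_size))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      rows <- sample(nrow(X), subsample_size)
      grow_itree(X[rows, , drop = FALSE], depth = 0L, max_depth = max_depth)
    })
  })
  structure(list(trees = trees, n_trees = n_trees,
                 subsample_size = subsample_size, max_depth = max_depth,
                 n_features = ncol(X), seed = as.integer(seed)),
            class = "isolation_forest")
}

# recursive isolation tree: leaf = list(size); split = list(attr, value, l, r)
grow_itree <- function(X, depth, max_depth) {
  n <- nrow(X)
  if (n <= 1L || depth >= max_depth) return(list(size = n))
  rng <- apply(X, 2, range)
  usable <- which(rng[2, ] > rng[1, ])
  if (!length(usable)) return(list(size = n))  # all rows identical
  q <- if (length(usable) == 1L) usable else sample(usable, 1L)
  sv <- runif(1, rng[1, q], rng[2, q])
  left <- X[, q] < sv
  list(attr = q, value = sv,
       l = grow_itree(X[left, , drop = FALSE], depth + 1L, max_depth),
       r = grow_itree(X[!left, , drop = FALSE], depth + 1L, max_depth))
}

# average unsuccessful-BST search path length c(n)
avg_path_length <- function(n) {
  ifelse(n > 2, 2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n,
         ifelse(n == 2, 1, 0))
}

# path lengths of all rows of X through one tree (iterative set routing)
tree_path_lengths <- function(tree, X) {
  h <- numeric(nrow(X))
  recurse <- function(node, idx, depth) {
    if (!length(idx)) return()
    if (is.null(node$attr)) {
      h[idx] <<- depth + avg_path_length(node$size)
      return()
    }
    left <- X[idx, node$attr] < node$value
    recurse(node$l, idx[left], depth + 1)
    recurse(node$r, idx[!left], depth + 1)
  }
  recurse(tree, seq_len(nrow(X)), 0)
  h
}

#' @rdname fit_isolation_forest
#' @param model a fitted `isolation_forest`.
#' @return `anomaly_scores()` returns a numeric vector of scores in (0, 1).
#' @export
anomaly_scores <- function(model, X) {
  stopifnot(inherits(model, "isolation_forest"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    abort(sprintf("model was fitted on %d features, data has %d",
                  model$n_features, ncol(X)))
  }
  H <- vapply(model$trees, function(tr) tree_path_lengths(tr, X),
              numeric(nrow(X)))
  eh <- rowMeans(matrix(H, nrow = nrow(X)))
  2^(-eh / avg_path_length(model$subsample_size))
}

#' Remove anomalous spectra with an isolation forest
#'
#' Fits an isolation forest to the reflectance matrix (raw spectra, before
#' any preprocessing) and removes the `floor(contamination * n)`
#' highest-scoring rows, so the survivor count is deterministic. With
#' `by_class = TRUE` the screening runs independently within each variety,
#' mirroring per-variety quality control.
#'
#' @param table a spectra table.
#' @param contamination expected outlier proportion in (0, 0.5)
#'   (default 0.05).
#' @inheritParams fit_isolation_forest
#' @param by_class screen within each label separately (default `FALSE`).
#' @return A list with `clean` (the surviving rows, original order) and
#'   `report` (an `outlier_report`: tibble of ids, labels, scores and
#'   flags, plus the contamination used).
#' @export
filter_outliers <- function(table, contamination = 0.05, n_trees = 100,
                            subsample_size = NULL, seed = 1L,
                            by_class = FALSE) {
  check_proportion(contamination, "contamination", 0, 0.5, hi_open = TRUE)
  if (contamination <= 0) abort("`contamination` must be > 0")
  X <- spectra_matrix(table)
  n <- nrow(X)
  scores <- numeric(n)
  flagged <- logical(n)
  groups <- if (by_class) split(seq_len(n), table$label) else list(seq_len(n))
  for (g in groups) {
    ss <- if (is.null(subsample_size)) min(256, length(g)) else
      min(subsample_size, length(g))
    fit <- fit_isolation_forest(X[g, , drop = FALSE], n_trees = n_trees,
                                subsample_size = ss, seed = seed)
    sc <- anomaly_scores(fit, X[g, , drop = FALSE])
    scores[g] <- sc
    k <- floor(contamination * length(g))
    if (k > 0) flagged[g[order(sc, decreasing = TRUE)[seq_len(k)]]] <- TRUE
  }
  report <- structure(list(
    samples = tibble::tibble(id = table$id, label = table$label,
                             score = scores, flagged = flagged),
    contamination = contamination, n_removed = sum(flagged)
  ), class = "outlier_report")
  list(clean = table[!flagged, , drop = FALSE], report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Isolation-Forest screening: %d of %d samples flagged (contamination %.3f)\n",
    x$n_removed, nrow(x$samples), x$contamination))
  invisible(x)
}
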