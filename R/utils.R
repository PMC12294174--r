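#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif predict sd var prcomp quantile
NULL

# squared Euclidean distances between rows of X (and optionally rows of Z)
sq_dist <- function(X, Z = NULL) {
  X <- as.matrix(X)
  if (is.null(Z)) {
    G <- tcrossprod(X)
    d <- diag(G)
    D <- outer(d, d, "+") - 2 * G
  } else {
    Z <- as.matrix(Z)
    D <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  }
  D[D < 0] <- 0
  D
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

check_proportion <- function(x, name, lo = 0, hi = 1, hi_open = FALSE) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi ||
      (hi_open && x >= hi)) {
    abort(sprintf("`%s` must lie in [%g, %g%s", name, lo, hi,
                  if (hi_open) ")" else "]"))
  }
  x
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}
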