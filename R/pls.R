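#' Partial least squares regression (SIMPLS)
#'
#' A compact SIMPLS fit used as the regression core of CARS wavelength
#' selection. Predictors and responses are centered internally; the fit is
#' deterministic. Component extraction stops early if the score norm
#' collapses (rank deficiency); the achieved component count is recorded.
#'
#' @param X numeric predictor matrix, samples x bands.
#' @param Y numeric response matrix (or vector), samples x responses.
#' @param n_components maximum number of latent components; capped at
#'   `min(n - 1, ncol(X))`.
#' @return An object of class `pls_model` with weights, loadings, scores,
#'   the per-component-count coefficient array, and centering means.
#' @references de Jong (1993), SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics Intell. Lab. Syst. 18, 251-263.
#' @export
pls_fit <- function(X, Y, n_components) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) abort("X and Y row counts differ")
  A <- min(check_count(n_components, "n_components"), n - 1L, ncol(X))
  xmean <- colMeans(X)
  ymean <- colMeans(Y)
  Xc <- sweep(X, 2, xmean)
  Yc <- sweep(Y, 2, ymean)
  p <- ncol(X); K <- ncol(Y)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, p, A); TT <- matrix(0, n, A)
  P <- matrix(0, p, A); Q <- matrix(0, K, A); V <- matrix(0, p, A)
  achieved <- 0L
  for (a in seq_len(A)) {
    q <- if (K == 1L) 1 else eigen(crossprod(S), symmetric = TRUE)$vectors[, 1]
    r <- S %*% q
    t <- Xc %*% r
    normt <- sqrt(sum(t^2))
    if (!is.finite(normt) || normt < 1e-12) break
    t <- t / normt; r <- r / normt
    pl <- crossprod(Xc, t)
    ql <- crossprod(Yc, t)
    v <- pl
    if (a > 1) {
      v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1), drop = FALSE], pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t; P[, a] <- pl; Q[, a] <- ql; V[, a] <- v
    achieved <- a
  }
  if (achieved == 0L) abort("no PLS component could be extracted")
  idx <- seq_len(achieved)
  structure(list(
    n_components = achieved,
    weights = R[, idx, drop = FALSE],
    scores = TT[, idx, drop = FALSE],
    x_loadings = P[, idx, drop = FALSE],
    y_loadings = Q[, idx, drop = FALSE],
    coefficients = R[, idx, drop = FALSE] %*% t(Q[, idx, drop = FALSE]),
    x_means = xmean, y_means = ymean
  ), class = "pls_model")
}

#' @rdname pls_fit
#' @param model a fitted `pls_model`.
#' @param newdata predictor matrix to predict for.
#' @param ncomp number of components to use (default: all achieved).
#' @return `pls_predict()` returns the predicted response matrix.
#' @export
pls_predict <- function(model, newdata, ncomp = model$n_components) {
  stopifnot(inherits(model, "pls_model"))
  ncomp <- min(ncomp, model$n_components)
  idx <- seq_len(ncomp)
  Xc <- sweep(as.matrix(newdata), 2, model$x_means)
  B <- model$weights[, idx, drop = FALSE] %*%
    t(model$y_loadings[, idx, drop = FALSE])
  sweep(Xc %*% B, 2, model$y_means, "+")
}

# one-hot response coding for PLS on class labels
one_hot <- function(labels) {
  f <- as.factor(labels)
  Y <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

#' Cross-validated component selection (RMSECV)
#'
#' Splits samples into `folds` random folds, fits PLS on each training
#' portion, and pools squared held-out prediction errors over all entries
#' of the response matrix:
#' `RMSECV(a) = sqrt(mean((Y - Yhat_a)^2))`. Returns the component count
#' minimizing RMSECV and the minimum value. Deterministic given `seed`
#' (or an explicit `fold_id`).
#'
#' @inheritParams pls_fit
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer RNG seed for fold assignment.
#' @param fold_id optional explicit per-sample fold assignment, overriding
#'   the seeded draw.
#' @return A list: `best_ncomp`, `rmsecv` (the minimum), and
#'   `per_component` (RMSECV for 1..`n_components`).
#' @export
rmsecv <- function(X, Y, n_components, folds = 10, seed = 1L,
                   fold_id = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  folds <- check_count(folds, "folds", min = 2L)
  if (is.null(fold_id)) {
    fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  }
  if (min(table(fold_id)) < 2) abort("a fold has fewer than 2 samples")
  A <- min(n_components, ncol(X), n - max(table(fold_id)) - 1L)
  sse <- numeric(A)
  n_entries <- 0
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    fit <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], A)
    Xc <- sweep(X[!tr, , drop = FALSE], 2, fit$x_means)
    Tn <- Xc %*% fit$weights
    pred <- matrix(rep(fit$y_means, each = sum(!tr)), sum(!tr))
    for (a in seq_len(fit$n_components)) {
      pred <- pred + tcrossprod(Tn[, a], fit$y_loadings[, a])
      sse[a] <- sse[a] + sum((Y[!tr, , drop = FALSE] - pred)^2)
    }
    if (fit$n_components < A) {   # rank-limited fold: reuse last prediction
      for (a in seq(fit$n_components + 1, A)) {
        sse[a] <- sse[a] + sum((Y[!tr, , drop = FALSE] - pred)^2)
      }
    }
    n_entries <- n_entries + sum(!tr) * ncol(Y)
  }
  per_component <- sqrt(sse / n_entries)
  list(best_ncomp = which.min(per_component),
       rmsecv = min(per_component),
       per_component = per_component)
}
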