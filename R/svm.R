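#' Gaussian radial basis kernel
#'
#' `k(x, z) = exp(-g * ||x - z||^2)`, the kernel of the study's SVM; `g`
#' is the kernel-width hyperparameter tuned alongside the cost `C`.
#'
#' @param x,z numeric vectors of equal length.
#' @param g kernel parameter, > 0.
#' @return The kernel value in (0, 1\].
#' @export
rbf_kernel <- function(x, z, g) {
  if (length(x) != length(z)) abort("`x` and `z` lengths differ")
  if (g <= 0) abort("`g` must be > 0")
  exp(-g * sum((x - z)^2))
}

#' Fit a multi-class RBF-SVM with explicit kernel parameters
#'
#' A thin, reproducible wrapper around the `libsvm` C-classification
#' solver (one-vs-one voting) with the kernel fixed to
#' `exp(-g * ||x - z||^2)` on the features exactly as passed (no internal
#' rescaling), so `g` keeps the same meaning as [rbf_kernel()].
#'
#' @param X numeric training matrix, samples x bands.
#' @param y class labels.
#' @param C cost (penalty) parameter, > 0.
#' @param g RBF kernel parameter, > 0.
#' @return An object of class `rbf_svm`.
#' @export
fit_rbf_svm <- function(X, y, C, g) {
  if (C <= 0 || g <= 0) abort("`C` and `g` must be > 0")
  X <- as.matrix(X)
  y <- as.factor(y)
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = g, scale = FALSE)
  structure(list(fit = fit, n_features = ncol(X), levels = levels(y),
                 C = C, g = g),
            class = "rbf_svm")
}

#' @rdname fit_rbf_svm
#' @param object a fitted `rbf_svm`.
#' @param newdata matrix of spectra to classify.
#' @param ... unused.
#' @return `predict()` returns a factor of predicted labels.
#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) abort("feature count mismatch")
  pred <- predict(object$fit, newdata)
  factor(as.character(pred), levels = object$levels)
}

#' Cross-validated SVM misclassification fitness
#'
#' The fitness minimized during hyperparameter tuning: the stratified
#' k-fold cross-validation misclassification rate of the RBF-SVM on the
#' calibration rows, in \[0, 1\]. Deterministic given `seed` (or an
#' explicit `fold_id`).
#'
#' @inheritParams fit_rbf_svm
#' @param folds number of stratified folds (default 5); every class must
#'   have at least `folds` samples.
#' @param seed integer RNG seed for the fold assignment.
#' @param fold_id optional explicit fold assignment.
#' @return The pooled misclassification rate.
#' @export
svm_fitness <- function(C, g, X, y, folds = 5, seed = 1L, fold_id = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  folds <- check_count(folds, "folds", min = 2L)
  if (min(table(y)) < folds) {
    abort("every class needs at least `folds` samples for stratified CV")
  }
  fold_id <- fold_id %||% stratified_folds(y, folds, seed)
  wrong <- 0L
  for (k in sort(unique(fold_id))) {
    tr <- which(fold_id != k); te <- which(fold_id == k)
    fit <- fit_rbf_svm(X[tr, , drop = FALSE], y[tr], C = C, g = g)
    pred <- predict(fit, X[te, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(y[te]))
  }
  wrong / length(y)
}

#' Tune SVM hyperparameters with a population metaheuristic
#'
#' Minimizes [svm_fitness()] over the `(C, g)` box with one of the four
#' optimizers (population 15, 30 iterations by default). The fold
#' assignment is fixed once per run, so every `(C, g)` candidate is
#' scored on the same surface, and the first population member is
#' initialized at `(C, g) = (1, 1)`, so the tuned CV fitness can never
#' exceed the default's. With `fitness_max_per_class` set (default 30),
#' the CV fitness is evaluated on a seeded stratified subsample of the
#' calibration rows — a surrogate surface that keeps the 465-evaluation
#' search affordable — while the returned model is always refit on all
#' calibration rows at the best `(C, g)`.
#'
#' @inheritParams svm_fitness
#' @param algorithm one of `"gwo"`, `"pso"`, `"ga"`, `"zoa"`.
#' @param space the `(C, g)` box (default `[0.001, 100]^2`).
#' @param pop_size,max_iter optimizer budget (defaults 15 and 30).
#' @param fitness_max_per_class cap on rows per class used by the CV
#'   fitness; `Inf` uses every calibration row.
#' @return An object of class `svm_tune`: the refit `model`, `best_C`,
#'   `best_g`, `best_fitness` (CV error), and the full
#'   `optimizer` result.
#' @export
tune_svm <- function(X, y, algorithm = c("gwo", "pso", "ga", "zoa"),
                     space = search_space(c(0.001, 0.001), c(100, 100)),
                     pop_size = 15, max_iter = 30, folds = 5, seed = 1L,
                     fitness_max_per_class = 30L) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  y <- as.factor(y)
  sub <- seq_along(y)
  if (is.finite(fitness_max_per_class) &&
      any(table(y) > fitness_max_per_class)) {
    sub <- withr::with_seed(seed, unlist(lapply(split(sub, y), function(i) {
      if (length(i) > fitness_max_per_class) {
        sort(sample(i, fitness_max_per_class))
      } else i
    }), use.names = FALSE))
  }
  Xf <- X[sub, , drop = FALSE]
  yf <- y[sub]
  fold_id <- stratified_folds(yf, folds, seed)
  fitness <- function(v) {
    svm_fitness(v[1], v[2], Xf, yf, folds = folds, fold_id = fold_id)
  }
  opt <- mh_optimize(algorithm, fitness, space, pop_size = pop_size,
                     max_iter = max_iter, seed = seed,
                     init = c(1, 1))
  model <- fit_rbf_svm(X, y, C = opt$best_position[1],
                       g = opt$best_position[2])
  structure(list(model = model, best_C = opt$best_position[1],
                 best_g = opt$best_position[2],
                 best_fitness = opt$best_fitness,
                 optimizer = opt, algorithm = algorithm,
                 folds = folds, seed = as.integer(seed)),
            class = "svm_tune")
}

#' @export
print.svm_tune <- function(x, ...) {
  cat(sprintf("%s-tuned RBF-SVM: C = %.4g, g = %.4g, CV error = %.4f\n",
              toupper(x$algorithm), x$best_C, x$best_g, x$best_fitness))
  invisible(x)
}

#' Confusion-matrix evaluation of a classifier
#'
#' @param model a fitted `rbf_svm` (or `svm_tune`, whose refit model is
#'   used).
#' @param X matrix of spectra to classify.
#' @param y true labels; labels outside the model's training classes
#'   raise an error unless `allow_unknown = TRUE`, in which case they are
#'   counted in an explicit `"unknown"` row.
#' @param allow_unknown tolerate truth labels unseen in training.
#' @return A `classification_report`: `confusion` (truth rows x predicted
#'   columns), `accuracy` (percent), and `per_class` recall tibble.
#' @export
evaluate_classifier <- function(model, X, y, allow_unknown = FALSE) {
  if (inherits(model, "svm_tune")) model <- model$model
  stopifnot(inherits(model, "rbf_svm"))
  pred <- predict(model, X)
  lev <- model$levels
  unknown <- !(as.character(y) %in% lev)
  if (any(unknown) && !allow_unknown) {
    abort(sprintf("%d labels outside the training classes (e.g. '%s')",
                  sum(unknown), as.character(y)[unknown][1]))
  }
  truth_lev <- if (any(unknown)) c(lev, "unknown") else lev
  truth <- as.character(y)
  truth[unknown] <- "unknown"
  confusion <- table(truth = factor(truth, levels = truth_lev),
                     predicted = factor(as.character(pred), levels = lev))
  correct <- sum(diag(confusion[lev, lev]))
  per_class <- tibble::tibble(
    label = truth_lev,
    n = as.integer(rowSums(confusion)),
    recall = ifelse(rowSums(confusion) > 0,
                    vapply(truth_lev, function(l)
                      if (l %in% lev) confusion[l, l] else 0L,
                      numeric(1)) / rowSums(confusion), NA_real_)
  )
  structure(list(confusion = unclass(confusion),
                 accuracy = 100 * correct / sum(confusion),
                 per_class = per_class,
                 n = sum(confusion)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report: accuracy %.3f%% on %d samples\n",
              x$accuracy, x$n))
  invisible(x)
}

#' Principal component embedding of spectra
#'
#' Column-centered PCA via the singular value decomposition: orthonormal
#' loadings, scores, and explained variances sorted in decreasing order.
#'
#' @param X numeric matrix, samples x bands.
#' @param n_components number of components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return A list of class `pca_embedding`: `scores` (n x k), `loadings`
#'   (bands x k, orthonormal), `explained_variance`, and
#'   `explained_variance_ratio`.
#' @export
pca_embed <- function(X, n_components = 2) {
  X <- as.matrix(X)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    abort("`n_components` must be <= min(n - 1, bands)")
  }
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  structure(list(
    scores = fit$x[, seq_len(n_components), drop = FALSE],
    loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
    explained_variance = ev[seq_len(n_components)],
    explained_variance_ratio = ev[seq_len(n_components)] / sum(ev)
  ), class = "pca_embedding")
}
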