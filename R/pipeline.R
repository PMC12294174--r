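#' Run the full variety-classification pipeline
#'
#' Chains the whole workflow on a spectra table: Isolation-Forest outlier
#' screening on the raw reflectance, Kennard-Stone 3:1 per-class
#' splitting, preprocessing applied after the split (the MSC reference is
#' the calibration-set mean, so no statistic crosses the split), optional
#' CARS wavelength selection on the calibration rows, metaheuristic
#' SVM hyperparameter tuning, and confusion-matrix evaluation on both
#' sets.
#'
#' @param table a spectra table (e.g. from [generate_spectra()]); pass
#'   `screen = FALSE` if outliers were already removed.
#' @param preprocess one of `"none"`, `"baseline"`, `"msc"`, `"sg1st"`.
#' @param optimizer one of `"gwo"`, `"pso"`, `"ga"`, `"zoa"`.
#' @param cars run CARS wavelength selection before tuning
#'   (default `FALSE`).
#' @param screen run Isolation-Forest screening (default `TRUE`).
#' @param contamination screening contamination (default 0.05).
#' @param split_ratio calibration share for Kennard-Stone (default 0.75).
#' @param cars_n_mc CARS Monte Carlo runs (default 500).
#' @param folds CV folds for the tuning fitness (default 5).
#' @param pop_size,max_iter optimizer budget (defaults 15, 30).
#' @param seed integer seed driving every stochastic stage.
#' @return An object of class `pipeline_result` with the screening
#'   report, split, CARS result (or `NULL`), tuning result, and
#'   calibration/prediction `classification_report`s.
#' @export
run_pipeline <- function(table,
                         preprocess = c("sg1st", "none", "baseline", "msc"),
                         optimizer = c("gwo", "pso", "ga", "zoa"),
                         cars = FALSE, screen = TRUE, contamination = 0.05,
                         split_ratio = 0.75, cars_n_mc = 500, folds = 5,
                         pop_size = 15, max_iter = 30, seed = 1L) {
  preprocess <- match.arg(preprocess)
  optimizer <- match.arg(optimizer)
  seed <- as.integer(seed)

  screen_report <- NULL
  if (screen) {
    scr <- filter_outliers(table, contamination = contamination,
                           seed = seed)
    screen_report <- scr$report
    table <- scr$clean
  }

  split <- kennard_stone_split(table, ratio = split_ratio)
  X <- spectra_matrix(table)
  w <- spectra_wavelengths(table)
  y <- table$label
  X_cal <- X[split$calibration, , drop = FALSE]
  X_pred <- X[split$prediction, , drop = FALSE]
  y_cal <- y[split$calibration]
  y_pred <- y[split$prediction]

  # preprocessing statistics come from calibration rows only
  msc_reference <- NULL
  if (preprocess == "baseline") {
    X_cal <- baseline_correct(X_cal, w)
    X_pred <- baseline_correct(X_pred, w)
  } else if (preprocess == "msc") {
    msc_reference <- colMeans(X_cal)
    X_cal <- msc(X_cal, msc_reference)
    X_pred <- msc(X_pred, msc_reference)
  } else if (preprocess == "sg1st") {
    X_cal <- sg1st(X_cal, w)
    X_pred <- sg1st(X_pred, w)
  }

  cars_result <- NULL
  if (cars) {
    cars_result <- cars_select(X_cal, y_cal, n_mc = cars_n_mc,
                               seed = seed + 1L)
    X_cal <- X_cal[, cars_result$selected, drop = FALSE]
    X_pred <- X_pred[, cars_result$selected, drop = FALSE]
  }

  # band autoscaling before the SVM: one (C, g) box across preprocessing
  # variants; statistics from calibration rows only
  X_cal <- standardize_bands(X_cal)
  X_pred <- standardize_bands(X_pred, stats = attr(X_cal, "stats"))

  tune <- tune_svm(X_cal, y_cal, algorithm = optimizer, folds = folds,
                   pop_size = pop_size, max_iter = max_iter,
                   seed = seed + 2L)
  structure(list(
    screen_report = screen_report,
    split = split,
    preprocess = preprocess,
    msc_reference = msc_reference,
    scaling_stats = attr(X_cal, "stats"),
    optimizer = optimizer,
    cars_result = cars_result,
    tune = tune,
    calibration_report = evaluate_classifier(tune, X_cal, y_cal),
    prediction_report = evaluate_classifier(tune, X_pred, y_pred),
    wavelengths = w,
    seed = seed
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline (%s preprocessing, %s optimizer%s):\n",
              x$preprocess, toupper(x$optimizer),
              if (!is.null(x$cars_result)) ", CARS" else ""))
  if (!is.null(x$screen_report)) {
    cat(sprintf("  screening removed %d samples\n",
                x$screen_report$n_removed))
  }
  if (!is.null(x$cars_result)) {
    cat(sprintf("  CARS selected %d bands (%.2f%%)\n",
                length(x$cars_result$selected),
                x$cars_result$selected_fraction))
  }
  cat(sprintf("  best C = %.4g, g = %.4g (CV error %.4f)\n",
              x$tune$best_C, x$tune$best_g, x$tune$best_fitness))
  cat(sprintf("  calibration accuracy %.3f%% | prediction accuracy %.3f%%\n",
              x$calibration_report$accuracy, x$prediction_report$accuracy))
  invisible(x)
}
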