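#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted pipeline objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit detail of a
#' result (one row per iteration, band, sample or confusion cell);
#' `glance()` returns a one-row summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return A tibble.
#' @name jujuspec-tidiers
NULL

#' @rdname jujuspec-tidiers
#' @method tidy optimizer_result
#' @export
tidy.optimizer_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_fitness = x$trace)
}

#' @rdname jujuspec-tidiers
#' @method glance optimizer_result
#' @export
glance.optimizer_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, best_fitness = x$best_fitness,
                 evaluations = x$evaluations, iterations = length(x$trace))
}

#' @rdname jujuspec-tidiers
#' @method tidy cars_result
#' @export
tidy.cars_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$rmsecv_trace),
                 n_retained = x$n_retained,
                 rmsecv = x$rmsecv_trace,
                 best_ncomp = x$best_ncomp_trace)
}

#' @rdname jujuspec-tidiers
#' @method glance cars_result
#' @export
glance.cars_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_bands = x$n_bands,
                 selected_fraction = x$selected_fraction,
                 best_iteration = x$best_iteration,
                 rmsecv = min(x$rmsecv_trace))
}

#' @rdname jujuspec-tidiers
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  as.data.frame(as.table(x$confusion)) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' @rdname jujuspec-tidiers
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n,
                 n_classes = ncol(x$confusion))
}

#' @rdname jujuspec-tidiers
#' @method tidy outlier_report
#' @export
tidy.outlier_report <- function(x, ...) x$samples

#' @rdname jujuspec-tidiers
#' @method glance outlier_report
#' @export
glance.outlier_report <- function(x, ...) {
  tibble::tibble(n = nrow(x$samples), n_removed = x$n_removed,
                 contamination = x$contamination)
}

#' @rdname jujuspec-tidiers
#' @method tidy svm_tune
#' @export
tidy.svm_tune <- function(x, ...) tidy(x$optimizer)

#' @rdname jujuspec-tidiers
#' @method glance svm_tune
#' @export
glance.svm_tune <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, C = x$best_C, g = x$best_g,
                 cv_error = x$best_fitness,
                 evaluations = x$optimizer$evaluations)
}

#' @rdname jujuspec-tidiers
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    preprocess = x$preprocess,
    optimizer = x$optimizer,
    cars = !is.null(x$cars_result),
    n_bands_used = if (is.null(x$cars_result)) length(x$wavelengths)
                   else length(x$cars_result$selected),
    C = x$tune$best_C, g = x$tune$best_g,
    cv_error = x$tune$best_fitness,
    calibration_accuracy = x$calibration_report$accuracy,
    prediction_accuracy = x$prediction_report$accuracy
  )
}

#' Long (tidy) form of a spectra table
#'
#' @param table a spectra table.
#' @return A tibble with columns `id`, `label`, `wavelength`,
#'   `reflectance`.
#' @export
spectra_longer <- function(table) {
  tidyr::pivot_longer(
    dplyr::as_tibble(table)[, !names(table) %in% ".outlier_truth"],
    dplyr::all_of(names(table)[is_band_col(names(table))]),
    names_to = "wavelength", values_to = "reflectance",
    names_prefix = "wavelength_", names_transform = as.numeric)
}
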