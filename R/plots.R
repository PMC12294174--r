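#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text labs theme_minimal scale_fill_gradient stat_summary
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: class-mean reflectance
#' curves for spectra tables, best-so-far fitness curves for optimizer
#' results, the RMSECV trace for CARS results, and a confusion-matrix
#' heat map for classification reports.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name jujuspec-autoplot
NULL

#' @rdname jujuspec-autoplot
#' @method autoplot spectra_tbl
#' @export
autoplot.spectra_tbl <- function(object, ...) {
  long <- spectra_longer(object)
  ggplot(long, aes(x = .data$wavelength, y = .data$reflectance,
                   colour = .data$label)) +
    stat_summary(fun = mean, geom = "line") +
    labs(x = "wavelength (nm)", y = "mean reflectance",
         colour = "variety") +
    theme_minimal()
}

#' @rdname jujuspec-autoplot
#' @method autoplot optimizer_result
#' @export
autoplot.optimizer_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iteration, y = .data$best_fitness)) +
    geom_line() + geom_point(size = 0.8) +
    labs(title = sprintf("%s fitness curve", toupper(object$algorithm)),
         x = "iteration", y = "best fitness so far") +
    theme_minimal()
}

#' @rdname jujuspec-autoplot
#' @method autoplot cars_result
#' @export
autoplot.cars_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iteration, y = .data$rmsecv)) +
    geom_line() +
    geom_point(data = tidy(object)[object$best_iteration, ],
               colour = "red") +
    labs(x = "sampling run", y = "RMSECV") +
    theme_minimal()
}

#' @rdname jujuspec-autoplot
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 2.5) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "true class",
         title = sprintf("accuracy %.2f%%", object$accuracy)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
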