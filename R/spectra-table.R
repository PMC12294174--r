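#' Spectra tables
#'
#' A spectra table is a tibble with one row per sample: an `id` column, a
#' `label` column (variety), optionally a logical `.outlier_truth` column
#' (synthetic data only), and one `wavelength_<nm>` column per spectral band.
#' Band wavelengths are carried in the column names, so the table survives
#' any dplyr manipulation without losing its grid.
#'
#' @param reflectance numeric matrix, samples x bands.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, length equal to `ncol(reflectance)`.
#' @param labels per-sample class labels.
#' @param ids per-sample unique identifiers; generated when `NULL`.
#' @param outlier_truth optional logical vector flagging synthetic outliers.
#' @return A tibble of class `spectra_tbl`.
#' @export
spectra_tbl <- function(reflectance, wavelengths, labels, ids = NULL,
                        outlier_truth = NULL) {
  reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  if (length(wavelengths) != ncol(reflectance)) {
    abort("`wavelengths` length must equal the number of spectral bands")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing")
  }
  if (!all(is.finite(reflectance))) abort("reflectance values must be finite")
  if (length(labels) != n) abort("`labels` length must equal the row count")
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  if (length(ids) != n) abort("`ids` length must equal the row count")
  if (anyDuplicated(ids)) abort("`ids` must be unique")
  out <- tibble::tibble(id = as.character(ids), label = as.character(labels))
  if (!is.null(outlier_truth)) {
    if (length(outlier_truth) != n) {
      abort("`outlier_truth` length must equal the row count")
    }
    out$.outlier_truth <- as.logical(outlier_truth)
  }
  bands <- tibble::as_tibble(reflectance, .name_repair = "minimal")
  names(bands) <- band_names(wavelengths)
  out <- dplyr::bind_cols(out, bands)
  class(out) <- c("spectra_tbl", class(out))
  out
}

band_names <- function(wavelengths) {
  sprintf("wavelength_%.4f", wavelengths)
}

is_band_col <- function(nms) startsWith(nms, "wavelength_")

#' @rdname spectra_tbl
#' @param table a spectra table.
#' @export
spectra_wavelengths <- function(table) {
  nms <- names(table)[is_band_col(names(table))]
  as.numeric(sub("^wavelength_", "", nms))
}

#' @rdname spectra_tbl
#' @export
spectra_matrix <- function(table) {
  m <- as.matrix(table[, is_band_col(names(table)), drop = FALSE])
  rownames(m) <- table$id
  m
}

# replace the band block of a spectra table, keeping metadata columns
set_spectra_matrix <- function(table, m) {
  stopifnot(nrow(m) == nrow(table))
  table[, is_band_col(names(table))] <- tibble::as_tibble(m,
    .name_repair = "minimal")
  table
}

#' Read and write spectra tables as CSV
#'
#' The on-disk dialect is a plain UTF-8 CSV with `.` as the decimal mark:
#' an `id` column, a `label` column, optionally `.outlier_truth`, and one
#' `wavelength_<nm>` column per band.
#'
#' @param table a spectra table.
#' @param path file path.
#' @return `read_spectra_csv()` returns a `spectra_tbl`;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
write_spectra_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  w <- as.numeric(sub("^wavelength_", "", names(df)[is_band_col(names(df))]))
  spectra_tbl(
    reflectance = as.matrix(df[, is_band_col(names(df)), drop = FALSE]),
    wavelengths = w,
    labels = df$label,
    ids = df$id,
    outlier_truth = if (".outlier_truth" %in% names(df)) df$.outlier_truth
  )
}
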