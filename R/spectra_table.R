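#' Construct an object-wise spectra table
#'
#' The central container of the pipeline: one row per seed object, one
#' column per waveband, plus categorical annotations (endophyte status,
#' cultivar, batch date) used as class labels in modelling.
#'
#' @param X numeric matrix `n_objects x n_bands` of mean reflectance spectra.
#' @param wavelengths per-band wavelengths (nm), strictly increasing.
#' @param labels data.frame of per-object annotations, or `NULL`.
#' @param object_meta data.frame of per-object pixel counts/centroids, or `NULL`.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(X, wavelengths, labels = NULL, object_meta = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != length(wavelengths))
    stop_input("X has %d bands but %d wavelengths given", ncol(X), length(wavelengths))
  if (any(diff(wavelengths) <= 0))
    stop_input("wavelengths must be strictly increasing")
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    if (nrow(labels) != nrow(X))
      stop_input("labels has %d rows, X has %d", nrow(labels), nrow(X))
  }
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 labels = labels, object_meta = object_meta),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d objects x %d bands (%.0f-%.0f nm)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$labels))
    cat("labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a spectra table to selected bands
#'
#' @param table a [spectra_table()].
#' @param bands integer band indices or logical mask.
#' @return A spectra table carrying the corresponding wavelength subset.
#' @export
subset_bands <- function(table, bands) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.logical(bands)) bands <- which(bands)
  spectra_table(table$X[, bands, drop = FALSE], table$wavelengths[bands],
                labels = table$labels, object_meta = table$object_meta)
}

#' Write / read a spectra table as delimited text
#'
#' The CSV layout is `object_id`, the label columns, then one column per
#' wavelength (header = wavelength in nm). Round-trips within text
#' precision (15 significant digits).
#'
#' @param table a [spectra_table()].
#' @param path file path.
#' @return `read_spectra_table` returns a [spectra_table()].
#' @export
write_spectra_table <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  lab <- table$labels
  if (is.null(lab)) lab <- data.frame(row.names = seq_len(nrow(table$X)))
  df <- cbind(data.frame(object_id = seq_len(nrow(table$X))), lab,
              as.data.frame(signif(table$X, 15)))
  names(df)[(ncol(df) - ncol(table$X) + 1L):ncol(df)] <-
    sprintf("wl_%.15g", table$wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_table
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (length(wl_cols) == 0) stop_input("no wavelength (wl_*) columns in %s", path)
  wl <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  lab_cols <- setdiff(seq_along(df), c(wl_cols, which(names(df) == "object_id")))
  spectra_table(as.matrix(df[, wl_cols, drop = FALSE]), wl,
                labels = if (length(lab_cols)) df[, lab_cols, drop = FALSE] else NULL)
}
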