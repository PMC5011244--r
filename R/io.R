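#' Read a one-column signal file
#'
#' Accepts single-column CSV (with or without header) or
#' whitespace-delimited text.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_signal <- function(path) {
  first <- readLines(path, n = 1L)
  header <- is.na(suppressWarnings(as.numeric(
    strsplit(trimws(first), "[,\\s]+")[[1]][1])))
  sep <- if (grepl(",", first)) "," else ""
  v <- scan(path, what = numeric(), sep = if (sep == ",") "," else "",
            skip = if (header) 1L else 0L, quiet = TRUE)
  .check_signal(v)
}

#' Write a signal as single-column CSV
#'
#' @param x numeric vector.
#' @param path destination path.
#' @export
write_signal <- function(x, path) {
  write.csv(data.frame(value = as.numeric(x)), path, row.names = FALSE)
  invisible(path)
}

#' Write a decomposition as CSV
#'
#' Columns `imf1..imfK, residue`, one row per sample.
#'
#' @param d a `"mode_decomp"`.
#' @param path destination path.
#' @export
write_decomposition <- function(d, path) {
  stopifnot(inherits(d, "mode_decomp"))
  df <- as.data.frame(d$imfs)
  names(df) <- paste0("imf", seq_len(d$nimf))
  df$residue <- d$residue
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a decomposition written by [write_decomposition()]
#'
#' @param path CSV path.
#' @param method label to attach (default `"EMD"`).
#' @return A `"mode_decomp"` (its `source` is the reconstruction).
#' @export
read_decomposition <- function(path, method = "EMD") {
  df <- read.csv(path)
  stopifnot("residue" %in% names(df))
  imfs <- as.matrix(df[, setdiff(names(df), "residue"), drop = FALSE])
  res <- df$residue
  .new_decomposition(imfs, res, method, rowSums(imfs) + res)
}

#' Read a spectra dataset CSV
#'
#' Expected layout: first column sample id, second column concentration
#' (mg/dL), remaining columns absorbance with wavelength headers (numbers,
#' possibly prefixed, e.g. `wl_1450`).
#'
#' @param path CSV path.
#' @return A [spectra_dataset()].
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(ncol(df) >= 4)
  wl <- as.numeric(gsub("[^0-9.]+", "", names(df)[-(1:2)]))
  spectra_dataset(wl, as.matrix(df[, -(1:2), drop = FALSE]),
                  df[[2]], ids = as.character(df[[1]]))
}

#' Write a spectra dataset CSV
#'
#' @param dataset a [spectra_dataset()].
#' @param path destination path.
#' @export
write_spectra <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  df <- data.frame(id = dataset$ids, concentration = dataset$concentrations,
                   check.names = FALSE)
  ab <- as.data.frame(dataset$absorbance)
  names(ab) <- sprintf("%.4f", dataset$wavelengths)
  write.csv(cbind(df, ab), path, row.names = FALSE)
  invisible(path)
}
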