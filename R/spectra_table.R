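#' Per-seed mean spectra table
#'
#' Rows are seeds, columns are bands; each row holds one seed's mean
#' reflectance spectrum, with a class label, a side tag (`"embryo"`,
#' `"endosperm"` or `"both"`) and a seed id that links the two faces of the
#' same kernel.
#'
#' @param reflectance Numeric matrix, seeds x bands.
#' @param wavelengths Band centres in nm, one per column.
#' @param class Class label per seed (coerced to factor). May be `NA`.
#' @param side `"embryo"`, `"endosperm"` or `"both"` (scalar or per seed).
#' @param seed_id Integer seed identities (default `1:n`).
#' @return A `spectra_table` object.
#' @export
spectra_table <- function(reflectance, wavelengths, class = NA, side = "embryo",
                          seed_id = seq_len(nrow(reflectance))) {
  stopifnot(is.matrix(reflectance))
  check_wavelengths(wavelengths)
  if (ncol(reflectance) != length(wavelengths)) {
    stop("ncol(reflectance) must equal length(wavelengths)", call. = FALSE)
  }
  if (anyNA(reflectance)) stop("spectra must not contain missing values",
                               call. = FALSE)
  n <- nrow(reflectance)
  side <- rep_len(as.character(side), n)
  stopifnot(all(side %in% c("embryo", "endosperm", "both")))
  class <- rep_len(class, n)
  seed_id <- as.integer(rep_len(seed_id, n))
  if (anyDuplicated(seed_id)) stop("seed ids must be unique", call. = FALSE)
  colnames(reflectance) <- sprintf("band_%.2f", wavelengths)
  structure(list(reflectance = reflectance,
                 wavelengths = as.numeric(wavelengths),
                 class = factor(class), side = side, seed_id = seed_id),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d seeds x %d bands (%.1f-%.1f nm); sides: %s\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths), max(x$wavelengths),
              paste(unique(x$side), collapse = "/")))
  if (!all(is.na(x$class))) {
    print(table(class = x$class))
  }
  invisible(x)
}

#' @export
as.data.frame.spectra_table <- function(x, ...) {
  cbind(data.frame(seed_id = x$seed_id, class = as.character(x$class),
                   side = x$side, stringsAsFactors = FALSE),
        as.data.frame(x$reflectance))
}

#' @export
`[.spectra_table` <- function(x, i, ...) {
  spectra_table(x$reflectance[i, , drop = FALSE], x$wavelengths,
                class = as.character(x$class)[i], side = x$side[i],
                seed_id = x$seed_id[i])
}

#' Write / read a spectra table as CSV
#'
#' Layout: `seed_id,class,side,band_<nm>,...` with one row per seed.
#'
#' @param x A [spectra_table].
#' @param path CSV path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_table].
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  band_cols <- grep("^band_", names(df))
  if (length(band_cols) == 0L) stop("no band_<nm> columns in ", path,
                                    call. = FALSE)
  wl <- as.numeric(sub("^band_", "", names(df)[band_cols]))
  spectra_table(as.matrix(df[, band_cols, drop = FALSE]), wl,
                class = df$class, side = df$side, seed_id = df$seed_id)
}
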