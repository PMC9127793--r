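#' Hyperspectral data cube
#'
#' A hypercube is a 3-D reflectance (or raw-count) array of dimension
#' rows x cols x bands together with the band-centre wavelengths in nm and a
#' provenance state, either `"raw"` (camera counts, not yet corrected) or
#' `"corrected"` (unitless reflectance after white/dark calibration).
#'
#' @param values 3-D numeric array, rows x cols x bands.
#' @param wavelengths Numeric vector of band centres in nm, strictly
#'   increasing, one per band.
#' @param state `"raw"` or `"corrected"`.
#' @return An object of class `hypercube` with elements `values`,
#'   `wavelengths` and `state`.
#' @export
hypercube <- function(values, wavelengths, state = c("raw", "corrected")) {
  state <- match.arg(state)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  check_wavelengths(wavelengths)
  if (dim(values)[3L] != length(wavelengths)) {
    stop("third dimension of `values` must match length(wavelengths)",
         call. = FALSE)
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 state = state),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), state: %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              x$state))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

# Flatten to a (rows*cols) x bands matrix; pixel p maps to
# (row, col) = (1 + (p-1) %% rows, 1 + (p-1) %/% rows), i.e. column-major.
cube_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, d[1L] * d[2L], d[3L])
}

# Accept white/dark references either as a full rows x cols x bands frame or
# as a cols x bands line average (the natural output of a line-scan system,
# one spectrum per cross-track pixel). A plain 2-D spatial frame is rejected:
# illumination and dark current are wavelength dependent, so references must
# resolve the band axis.
ref_band_plane <- function(ref, band, nrow_cube, ncol_cube, nband, what) {
  d <- dim(ref)
  if (length(d) == 3L) {
    if (!all(d == c(nrow_cube, ncol_cube, nband))) {
      stop(sprintf("%s reference dimensions do not match the cube", what),
           call. = FALSE)
    }
    return(ref[, , band])
  }
  if (length(d) == 2L) {
    if (!all(d == c(ncol_cube, nband))) {
      stop(sprintf(
        "%s reference must be rows x cols x bands or cols x bands; got %d x %d",
        what, d[1L], d[2L]), call. = FALSE)
    }
    # broadcast the per-column spectrum down the scan (row) axis
    return(matrix(ref[, band], nrow_cube, ncol_cube, byrow = TRUE))
  }
  stop(sprintf("%s reference must be a 2-D or 3-D array", what),
       call. = FALSE)
}

#' Radiometric calibration of a raw hypercube
#'
#' Converts raw camera counts to relative reflectance with the standard
#' flat-field correction `Rc = (Rraw - Rdark) / (Rwhite - Rdark)`, applied
#' elementwise per band. The white reference is an image of a
#' high-reflectance (Teflon) standard; the dark reference is collected with
#' the light off and the lens capped, and removes the CCD dark current.
#'
#' Pixels where `white == dark` would divide by zero; they are set to 0 and
#' counted in the `n_degenerate` attribute of the result. If more than 1% of
#' pixel-band entries are degenerate a warning is raised.
#'
#' @param raw A `hypercube` with `state = "raw"`.
#' @param white,dark Reference frames, either rows x cols x bands arrays or
#'   cols x bands matrices (per-column line averages, broadcast along the
#'   scan axis). Both must use the same layout as each other.
#' @return A corrected `hypercube` (reflectance, `state = "corrected"`) with
#'   attribute `n_degenerate`.
#' @export
calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$state != "raw") {
    stop("`raw` must have state \"raw\"; refusing to re-calibrate", call. = FALSE)
  }
  d <- dim(raw$values)
  out <- raw$values
  n_deg <- 0L
  for (b in seq_len(d[3L])) {
    w <- ref_band_plane(white, b, d[1L], d[2L], d[3L], "white")
    k <- ref_band_plane(dark,  b, d[1L], d[2L], d[3L], "dark")
    den <- w - k
    bad <- den == 0
    n_deg <- n_deg + sum(bad)
    den[bad] <- 1
    plane <- (raw$values[, , b] - k) / den
    plane[bad] <- 0
    out[, , b] <- plane
  }
  total <- prod(d)
  if (n_deg > 0.01 * total) {
    warning(sprintf("calibration: %d of %d entries (%.1f%%) had white == dark",
                    n_deg, total, 100 * n_deg / total), call. = FALSE)
  }
  res <- hypercube(out, raw$wavelengths, state = "corrected")
  attr(res, "n_degenerate") <- n_deg
  res
}

#' Crop a hypercube to a wavelength window
#'
#' Retains bands with `lo_nm <= wavelength <= hi_nm` (inclusive on both
#' ends). Used to discard the noisy spectral edges of the detector; on the
#' default synthetic instrument grid, cropping to 1000-2000 nm keeps 159
#' bands.
#'
#' @param cube A `hypercube`.
#' @param lo_nm,hi_nm Window bounds in nm, `lo_nm < hi_nm`.
#' @return A `hypercube` restricted to the window.
#' @export
crop_bands <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hypercube"), lo_nm < hi_nm)
  keep <- cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm
  if (!any(keep)) {
    stop(sprintf("no bands in [%g, %g] nm", lo_nm, hi_nm), call. = FALSE)
  }
  hypercube(cube$values[, , keep, drop = FALSE], cube$wavelengths[keep],
            state = cube$state)
}
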