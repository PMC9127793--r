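# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Index of the band nearest to a target wavelength
#'
#' @param wavelengths Numeric vector of band centres in nm, strictly increasing.
#' @param nm Target wavelength in nm.
#' @return Integer band index.
#' @export
nearest_band <- function(wavelengths, nm) {
  stopifnot(is.numeric(wavelengths), length(wavelengths) >= 1L,
            is.numeric(nm), length(nm) == 1L, is.finite(nm))
  which.min(abs(wavelengths - nm))
}

# Draw `n` independent sub-seeds from one master seed, so that each stage of a
# simulation has its own reproducible stream without touching global RNG state.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

check_wavelengths <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 1L ||
      anyNA(wavelengths) || any(!is.finite(wavelengths))) {
    stop("`wavelengths` must be a finite numeric vector", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  }
  invisible(wavelengths)
}
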