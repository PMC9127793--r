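# Quality-control graphics: quick-look files for checking segmentation and
# the band-ratio search. These are side outputs for humans; nothing in the
# pipeline reads them back.

#' Write a segmentation overlay PNG
#'
#' Gray-scale masking-band image with the mask boundary burned in red, for
#' eyeballing segmentation quality.
#'
#' @param cube Corrected [hypercube].
#' @param mask Logical mask from [build_mask()].
#' @param path Output `.png` path.
#' @param mask_nm Band to show (defaults to the band the mask was built from).
#' @return Invisibly, `path`.
#' @export
write_mask_overlay <- function(cube, mask, path,
                               mask_nm = attr(mask, "band_nm") %||% 1098) {
  b <- nearest_band(cube$wavelengths, mask_nm)
  img <- cube$values[, , b]
  img <- (img - min(img)) / max(max(img) - min(img), .Machine$double.eps)
  boundary <- mask & !(rbind(FALSE, mask[-nrow(mask), ]) &
                         rbind(mask[-1, ], FALSE) &
                         cbind(FALSE, mask[, -ncol(mask)]) &
                         cbind(mask[, -1], FALSE))
  rgb <- array(img, c(dim(img), 3L))
  rgb[, , 1][boundary] <- 1
  rgb[, , 2][boundary] <- 0
  rgb[, , 3][boundary] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write the band-pair F-value contour PNG
#'
#' Filled-contour rendering of `log10(1 + F)` over all numerator x
#' denominator wavelength pairs, with the selected pair marked.
#'
#' @param search A `band_ratio_search` from [search_ratios()].
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_f_contour <- function(search, path) {
  f <- log10(1 + search$f_matrix)
  f[!is.finite(f)] <- NA
  grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::filled.contour(
    search$wavelengths, search$wavelengths, f,
    color.palette = grDevices::hcl.colors,
    xlab = "numerator wavelength (nm)",
    ylab = "denominator wavelength (nm)",
    main = sprintf("log10(1 + F); best %.0f nm / %.0f nm",
                   search$best_pair[["num_nm"]],
                   search$best_pair[["den_nm"]]),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(search$best_pair[["num_nm"]],
                       search$best_pair[["den_nm"]],
                       pch = 4, cex = 2, lwd = 3)
    })
  invisible(path)
}

#' Write a per-seed ratio image PNG
#'
#' Ratio values are stretched by the quantizer bounds to `[0, 1]`
#' (background rendered black) -- a quick look at the texture input.
#'
#' @param img Ratio image from [ratio_image()].
#' @param q A `quantizer`.
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_ratio_png <- function(img, q, path) {
  z <- (img - q$lo) / max(q$hi - q$lo, .Machine$double.eps)
  z <- pmin(pmax(z, 0), 1)
  z[is.na(z)] <- 0
  png::writePNG(z, path)
  invisible(path)
}
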