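# Seed segmentation and per-seed spectrum extraction. The foreground mask
# is thresholded from the single band image with the best seed/background
# contrast (1098 nm on the study instrument), cleaned morphologically, and
# split into 8-connected single-seed regions.

#' Build the foreground seed mask from one band image
#'
#' Selects the band nearest `mask_nm`, thresholds it (Otsu's method on the
#' gray-level histogram unless an explicit threshold is given), fills
#' interior holes and removes connected specks smaller than `min_area`
#' pixels.
#'
#' @param cube A corrected [hypercube].
#' @param mask_nm Wavelength (nm) of the masking band; 1098 nm gives the
#'   highest seed/background contrast on the study instrument.
#' @param min_area Minimum component area in pixels; smaller specks are
#'   dropped.
#' @param threshold Optional explicit reflectance threshold overriding Otsu.
#' @return Logical matrix (TRUE = seed) with attributes `threshold` and
#'   `band_nm`.
#' @export
build_mask <- function(cube, mask_nm = 1098, min_area = 30, threshold = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$state != "corrected") {
    stop("`cube` must be calibrated before masking", call. = FALSE)
  }
  b <- nearest_band(cube$wavelengths, mask_nm)
  img <- cube$values[, , b]
  if (is.null(threshold)) {
    clamped <- pmin(pmax(img, 0), 1)
    threshold <- EBImage::otsu(EBImage::Image(clamped), range = c(0, 1))
  }
  mask <- img > threshold
  if (!any(mask) || all(mask)) {
    stop("segmentation error: mask is entirely fore- or background",
         call. = FALSE)
  }
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- as.matrix(filled) > 0
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area)
    if (length(drop) > 0L) mask[lab %in% drop] <- FALSE
  }
  if (!any(mask)) {
    stop("segmentation error: no component of at least min_area pixels",
         call. = FALSE)
  }
  attr(mask, "threshold") <- as.numeric(threshold)
  attr(mask, "band_nm") <- cube$wavelengths[b]
  mask
}

# 8-connected component labelling by iterated minimum-label propagation.
# Each foreground pixel starts with its own linear index as label and
# repeatedly adopts the minimum label among its 8 neighbours until the
# labelling stabilises; labels are then compacted to 1..n.
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    r_src <- max(1, 1 - dr):min(h, h - dr)
    c_src <- max(1, 1 - dc):min(w, w - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      new <- pmin(new, shift(lab, offs[i, 1L], offs[i, 2L]))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, h, w)
  if (any(mask)) {
    roots <- lab[mask]
    out[mask] <- as.integer(factor(roots))
  }
  out
}

#' Split a foreground mask into single-seed regions
#'
#' Components are 8-connected; touching seeds therefore merge into one
#' region (a documented limitation -- no watershed splitting is attempted).
#' Regions are relabelled in raster order of their centroids (row-major).
#'
#' @param mask Logical matrix from [build_mask()].
#' @param min_area Minimum region area in pixels.
#' @return List of `seed_region` objects, each with `label`, `pixels`
#'   (n x 2 matrix of row, col), `centroid`, `area`.
#' @export
split_seeds <- function(mask, min_area = 30) {
  if (!any(mask)) stop("segmentation error: empty mask", call. = FALSE)
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) stop("segmentation error: zero components", call. = FALSE)
  regions <- vector("list", n)
  keep <- logical(n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    keep[k] <- TRUE
    regions[[k]] <- list(pixels = unname(idx), centroid = colMeans(idx),
                         area = nrow(idx))
  }
  regions <- regions[keep]
  if (length(regions) == 0L) {
    stop("segmentation error: all components below min_area", call. = FALSE)
  }
  cent <- t(vapply(regions, `[[`, numeric(2), "centroid"))
  ord <- order(cent[, 1L], cent[, 2L])
  regions <- regions[ord]
  for (k in seq_along(regions)) {
    regions[[k]]$label <- k
    class(regions[[k]]) <- "seed_region"
  }
  regions
}

#' Mean spectrum of a seed region
#'
#' Unweighted arithmetic mean over the region's pixels, per band.
#'
#' @param cube A [hypercube].
#' @param region A `seed_region` from [split_seeds()].
#' @return Numeric vector, one reflectance per band.
#' @export
mean_spectrum <- function(cube, region) {
  stopifnot(inherits(cube, "hypercube"))
  px <- region$pixels
  if (is.null(px) || nrow(px) == 0L) {
    stop("empty region", call. = FALSE)
  }
  d <- dim(cube$values)
  if (any(px[, 1L] < 1L | px[, 1L] > d[1L] | px[, 2L] < 1L | px[, 2L] > d[2L])) {
    stop("region extends outside the cube", call. = FALSE)
  }
  m <- cube_matrix(cube)
  lin <- px[, 1L] + (px[, 2L] - 1L) * d[1L]
  colMeans(m[lin, , drop = FALSE])
}

#' Pixel spectra of a seed region
#'
#' Returns the full pixels x bands reflectance matrix of one region along
#' with the pixel coordinates, as needed to build per-seed band-ratio
#' images for texture extraction.
#'
#' @inheritParams mean_spectrum
#' @return List with `values` (pixels x bands matrix) and `coords`
#'   (pixels x 2 row/col matrix).
#' @export
seed_pixel_values <- function(cube, region) {
  px <- region$pixels
  if (is.null(px) || nrow(px) == 0L) stop("empty region", call. = FALSE)
  d <- dim(cube$values)
  m <- cube_matrix(cube)
  lin <- px[, 1L] + (px[, 2L] - 1L) * d[1L]
  list(values = m[lin, , drop = FALSE], coords = px)
}

#' Extract a per-seed mean spectra table from a calibrated cube
#'
#' @param cube A corrected [hypercube].
#' @param regions Regions from [split_seeds()].
#' @param class Class label per region (or `NA`).
#' @param side Side tag for all rows.
#' @param seed_id Seed identities (default: region order).
#' @return A [spectra_table].
#' @export
extract_spectra <- function(cube, regions, class = NA, side = "embryo",
                            seed_id = seq_along(regions)) {
  x <- t(vapply(regions, function(r) mean_spectrum(cube, r),
                numeric(length(cube$wavelengths))))
  spectra_table(x, cube$wavelengths, class = class, side = side,
                seed_id = seed_id)
}

#' Assign ground-truth class labels to extracted regions
#'
#' Matches each region to the ground-truth seed whose mask it overlaps
#' most, and returns that seed's class label.
#'
#' @param regions Regions from [split_seeds()].
#' @param truth Ground truth from [generate_scene()].
#' @param image_dim Integer `c(rows, cols)`.
#' @return Integer vector of class ids, one per region (`NA` when a region
#'   overlaps no ground-truth seed).
#' @export
assign_labels <- function(regions, truth, image_dim) {
  h <- image_dim[1L]
  truth_lin <- lapply(truth$masks, function(px) px[, 1L] + (px[, 2L] - 1L) * h)
  vapply(regions, function(r) {
    lin <- r$pixels[, 1L] + (r$pixels[, 2L] - 1L) * h
    ov <- vapply(truth_lin, function(t) length(intersect(lin, t)), integer(1))
    if (max(ov) == 0L) return(NA_integer_)
    truth$class_id[which.max(ov)]
  }, integer(1))
}

#' Average the embryo- and endosperm-side spectra of each kernel
#'
#' Joins the two tables on `seed_id` (order-independent) and returns the
#' elementwise mean of each kernel's two rows, tagged `side = "both"`.
#' Class labels must agree between sides.
#'
#' @param embryo,endosperm Two [spectra_table]s covering the same seed ids
#'   on the same band grid.
#' @return A [spectra_table] with `side = "both"`.
#' @export
pair_and_average <- function(embryo, endosperm) {
  stopifnot(inherits(embryo, "spectra_table"),
            inherits(endosperm, "spectra_table"))
  if (!isTRUE(all.equal(embryo$wavelengths, endosperm$wavelengths))) {
    stop("band grids differ between sides", call. = FALSE)
  }
  if (!setequal(embryo$seed_id, endosperm$seed_id)) {
    stop("seed id mismatch between sides", call. = FALSE)
  }
  j <- match(embryo$seed_id, endosperm$seed_id)
  if (!identical(as.character(embryo$class),
                 as.character(endosperm$class)[j])) {
    stop("class labels disagree between sides for some seed id", call. = FALSE)
  }
  avg <- (embryo$reflectance + endosperm$reflectance[j, , drop = FALSE]) / 2
  spectra_table(avg, embryo$wavelengths, class = as.character(embryo$class),
                side = "both", seed_id = embryo$seed_id)
}
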