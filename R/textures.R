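# Image texture descriptors computed per seed from the optimal two-band
# ratio image: six first-order histogram statistics (HS) and four
# second-order gray-level co-occurrence matrix (GLCM) features at 0
# degrees, distance 1 pixel. Ratio values are linearly quantized to L gray
# levels using robust (1st-99th percentile) bounds estimated on the
# calibration set only.

#' Fit a gray-level quantizer on calibration ratio values
#'
#' @param values Numeric vector of ratio values (calibration-set pixels).
#' @param L Number of gray levels (default 64).
#' @param probs Percentile bounds of the linear stretch.
#' @return A `quantizer` list with `lo`, `hi`, `L`.
#' @export
make_quantizer <- function(values, L = 64L, probs = c(0.01, 0.99)) {
  stopifnot(L >= 2L, length(probs) == 2L)
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values", call. = FALSE)
  q <- stats::quantile(values, probs, names = FALSE, type = 7)
  structure(list(lo = q[1L], hi = q[2L], L = as.integer(L)),
            class = "quantizer")
}

#' Quantize ratio values to integer gray levels
#'
#' Linear stretch of `[lo, hi]` onto levels `0..L-1`, clamping outside
#' values to the end levels. Degenerate bounds (`hi == lo`) map everything
#' to level 0.
#'
#' @param x Numeric vector or matrix (NAs pass through).
#' @param q A `quantizer`.
#' @return Integer levels with the shape of `x`.
#' @export
quantize <- function(x, q) {
  stopifnot(inherits(q, "quantizer"))
  if (q$hi <= q$lo) {
    lev <- x
    lev[] <- 0L
    return(lev)
  }
  lev <- floor((x - q$lo) / (q$hi - q$lo) * q$L)
  lev <- pmin(pmax(lev, 0), q$L - 1L)
  storage.mode(lev) <- "integer"
  lev
}

#' Per-seed band-ratio image
#'
#' Builds the 2-D ratio image of one seed on its bounding box: numerator
#' band reflectance divided by denominator band reflectance at each mask
#' pixel, `NA` outside the mask.
#'
#' @param pix A list with `values` (pixels x bands) and `coords`
#'   (pixels x 2), as from [seed_pixel_values()].
#' @param num,den Band indices of the ratio.
#' @return Numeric matrix (bounding box) with `NA` background.
#' @export
ratio_image <- function(pix, num, den) {
  r <- pix$values[, num] / pix$values[, den]
  co <- pix$coords
  r0 <- min(co[, 1L]); c0 <- min(co[, 2L])
  img <- matrix(NA_real_, max(co[, 1L]) - r0 + 1L, max(co[, 2L]) - c0 + 1L)
  img[cbind(co[, 1L] - r0 + 1L, co[, 2L] - c0 + 1L)] <- r
  img
}

#' Histogram-statistics texture features
#'
#' First-order statistics of the gray-level histogram over the mask
#' pixels: mean intensity, mean consistency (sum of squared level
#' probabilities), skewness, kurtosis, mean contrast (the variance-form
#' spread) and entropy (in bits). Skewness and kurtosis are standardized
#' central moments by default, i.e. third and fourth central moments over
#' `s^3` and `s^4` with `s = sqrt(H_contrast)`; `as_printed = TRUE` instead
#' divides by `H_contrast^3` and `H_contrast^4` (the variance itself raised
#' to the power), for compatibility with sources that print the formulas
#' that way. A single-valued image has zero spread; its skewness and
#' kurtosis are defined as 0 and flagged.
#'
#' @param levels Integer vector of quantized gray levels (mask pixels).
#' @param L Number of gray levels.
#' @param as_printed Use the literal variance-power denominators.
#' @return Named numeric vector `H_intensity`, `H_consistency`,
#'   `H_skewness`, `H_kurtosis`, `H_contrast`, `H_entropy`, with attribute
#'   `degenerate` when the image is single-valued.
#' @export
histogram_stats <- function(levels, L, as_printed = FALSE) {
  levels <- levels[!is.na(levels)]
  if (length(levels) < 2L) stop("need at least 2 mask pixels", call. = FALSE)
  stopifnot(all(levels >= 0), all(levels < L))
  p <- tabulate(levels + 1L, nbins = L) / length(levels)
  z <- 0:(L - 1L)
  mu <- sum(z * p)
  consistency <- sum(p^2)
  contrast <- sum((z - mu)^2 * p)
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  degenerate <- contrast == 0
  if (degenerate) {
    skew <- 0
    kurt <- 0
  } else {
    m3 <- sum((z - mu)^3 * p)
    m4 <- sum((z - mu)^4 * p)
    if (as_printed) {
      skew <- m3 / contrast^3
      kurt <- m4 / contrast^4
    } else {
      s <- sqrt(contrast)
      skew <- m3 / s^3
      kurt <- m4 / s^4
    }
  }
  out <- c(H_intensity = mu, H_consistency = consistency,
           H_skewness = skew, H_kurtosis = kurt,
           H_contrast = contrast, H_entropy = entropy)
  attr(out, "degenerate") <- degenerate
  out
}

#' Gray-level co-occurrence matrix at 0 degrees, distance 1
#'
#' Counts horizontal pixel pairs (each pixel with the pixel one column to
#' its right) where both pixels lie inside the mask, and normalizes the
#' count matrix to sum 1. The matrix is not symmetrized: the (left, right)
#' order is kept as-is.
#'
#' @param img Integer matrix of quantized levels with `NA` outside the
#'   mask.
#' @param L Number of gray levels.
#' @return L x L matrix of pair probabilities (rows = left pixel level).
#' @export
glcm <- function(img, L) {
  stopifnot(is.matrix(img), L >= 1L)
  if (ncol(img) < 2L) stop("no valid horizontal pixel pair", call. = FALSE)
  a <- img[, -ncol(img), drop = FALSE]
  b <- img[, -1L, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid horizontal pixel pair", call. = FALSE)
  av <- a[ok]; bv <- b[ok]
  stopifnot(all(av >= 0), all(av < L), all(bv >= 0), all(bv < L))
  counts <- matrix(tabulate(av * L + bv + 1L, nbins = L * L), L, L,
                   byrow = TRUE)
  counts / sum(counts)
}

#' GLCM texture features
#'
#' Contrast, correlation, energy and homogeneity of a normalized
#' co-occurrence matrix, with marginal means/SDs defined from the row and
#' column sums. A matrix whose marginals have zero spread (e.g. from a
#' constant image) has undefined correlation; it is returned as 0 and
#' flagged.
#'
#' @param P Normalized co-occurrence matrix (sums to 1).
#' @return Named numeric vector `G_contrast`, `G_correlation`, `G_energy`,
#'   `G_homogeneity`, with attribute `degenerate_correlation`.
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1", call. = FALSE)
  L <- nrow(P)
  i <- matrix(0:(L - 1L), L, L)              # row level
  j <- t(i)                                  # column level
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  lev <- 0:(L - 1L)
  mu_i <- sum(lev * pi_)
  mu_j <- sum(lev * pj_)
  sd_i <- sqrt(sum((lev - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((lev - mu_j)^2 * pj_))
  contrast <- sum(abs(i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  degenerate <- sd_i * sd_j == 0
  correlation <- if (degenerate) 0 else
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  out <- c(G_contrast = contrast, G_correlation = correlation,
           G_energy = energy, G_homogeneity = homogeneity)
  attr(out, "degenerate_correlation") <- degenerate
  out
}

#' All 10 texture features of one seed's ratio image
#'
#' @param img Numeric ratio image (NA background), as from
#'   [ratio_image()].
#' @param q A `quantizer` fitted on calibration-set ratio values.
#' @param as_printed Passed to [histogram_stats()].
#' @return Named numeric vector of the 6 HS then 4 GLCM features.
#' @export
texture_vector <- function(img, q, as_printed = FALSE) {
  lev <- quantize(img, q)
  hs <- histogram_stats(lev[!is.na(lev)], q$L, as_printed = as_printed)
  g <- glcm_features(glcm(lev, q$L))
  c(hs, g)
}

#' Column-wise standard normalization with calibration-set statistics
#'
#' Centres and scales each feature column to zero mean and unit SD using
#' the mean/SD of the fit (calibration) rows only; all rows -- including
#' prediction rows -- are transformed with those stored statistics.
#' Zero-SD columns are set to 0 and flagged.
#'
#' @param x Numeric feature matrix.
#' @param fit_rows Indices (or logical mask) of the calibration rows.
#' @return List with `x` (normalized matrix), `center`, `scale`,
#'   `zero_sd` (logical per column).
#' @export
normalize_features <- function(x, fit_rows) {
  stopifnot(is.matrix(x))
  fit <- x[fit_rows, , drop = FALSE]
  if (nrow(fit) < 2L) stop("need at least 2 calibration rows", call. = FALSE)
  ctr <- colMeans(fit)
  scl <- apply(fit, 2L, stats::sd)
  zero <- scl == 0
  scl[zero] <- 1
  out <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  out[, zero] <- 0
  list(x = out, center = ctr, scale = scl, zero_sd = zero)
}
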