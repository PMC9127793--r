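# PCA route: principal components as low-dimensional model inputs, and
# feature wavelengths read off the peaks and valleys of the third
# component's loading curve (the first PC loading is typically flat for
# these spectra and carries no localized features).

#' Fit a principal component model to per-seed spectra
#'
#' Column-mean-centred PCA of the reflectance matrix, no scaling (the
#' spectra are already on a common reflectance scale). Loadings follow a
#' deterministic sign convention: the largest-magnitude element of each
#' loading is positive, which makes fits reproducible across platforms.
#'
#' @param x A [spectra_table] or a seeds x bands numeric matrix.
#' @param k Number of components to retain.
#' @param wavelengths Band grid (required when `x` is a bare matrix).
#' @return A `pca_model` with `loadings` (bands x k, unit columns),
#'   `explained_variance_ratio`, `scores` (seeds x k), `center` and
#'   `wavelengths`.
#' @export
fit_pca <- function(x, k = 3, wavelengths = NULL) {
  if (inherits(x, "spectra_table")) {
    wavelengths <- x$wavelengths
    x <- x$reflectance
  }
  stopifnot(is.matrix(x), k >= 1)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(x))
  if (k > min(nrow(x), ncol(x))) {
    stop("k must not exceed min(seeds, bands)", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- sprintf("band_%.2f", wavelengths)
  structure(list(loadings = loadings,
                 explained_variance_ratio = evr[seq_len(k)],
                 scores = scores, center = pr$center,
                 wavelengths = as.numeric(wavelengths), k = as.integer(k)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d bands; EVR: %s\n",
              x$k, nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Project spectra onto a fitted principal component model
#'
#' Uses only the stored centring vector and loadings, so prediction-set
#' rows never influence the fit.
#'
#' @param model A `pca_model`.
#' @param x A [spectra_table] or matrix on the same band grid as the fit.
#' @return Scores matrix, rows x k.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(x, "spectra_table")) {
    if (!isTRUE(all.equal(x$wavelengths, model$wavelengths))) {
      stop("band grid differs from the fitted model", call. = FALSE)
    }
    x <- x$reflectance
  }
  stopifnot(is.matrix(x))
  if (ncol(x) != nrow(model$loadings)) {
    stop("band count differs from the fitted model", call. = FALSE)
  }
  sweep(x, 2L, model$center) %*% model$loadings
}

# Interior local extrema of a 1-D signal with topographic prominence.
# For a peak, prominence = height minus the higher of the two minima
# encountered walking left/right until a strictly higher point (or the
# signal edge). Valleys are peaks of the negated signal.
find_extrema <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), type = character(),
                                prominence = numeric()))
  peak_prom <- function(v, i) {
    base_l <- v[i]
    j <- i - 1L
    while (j >= 1L && v[j] <= v[i]) { base_l <- min(base_l, v[j]); j <- j - 1L }
    base_r <- v[i]
    j <- i + 1L
    while (j <= n && v[j] <= v[i]) { base_r <- min(base_r, v[j]); j <- j + 1L }
    v[i] - max(base_l, base_r)
  }
  res <- list()
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L]) {
      p <- peak_prom(y, i)
      if (p >= min_prominence) res[[length(res) + 1L]] <-
          data.frame(index = i, type = "peak", prominence = p)
    } else if (y[i] < y[i - 1L] && y[i] < y[i + 1L]) {
      p <- peak_prom(-y, i)
      if (p >= min_prominence) res[[length(res) + 1L]] <-
          data.frame(index = i, type = "valley", prominence = p)
    }
  }
  if (length(res) == 0L) return(data.frame(index = integer(),
                                           type = character(),
                                           prominence = numeric()))
  do.call(rbind, res)
}

#' Feature wavelengths from the PC3 loading curve
#'
#' The peaks and valleys of the third component's loading ("weight
#' coefficient") curve mark the wavelengths that drive within-data
#' variation; they are returned, sorted, as the PCA-route feature
#' wavelengths. Extrema must clear a prominence threshold expressed as a
#' fraction of the loading's total range, so ripple is ignored. A flat
#' loading (range below `flat_eps`) yields an empty set with a warning.
#'
#' @param model A `pca_model` with at least 3 components.
#' @param prominence_frac Minimum extremum prominence as a fraction of the
#'   loading range (default 0.10).
#' @param component Which component's loading to scan (default 3).
#' @param flat_eps Absolute range below which the loading counts as flat.
#' @return List with `wavelengths` (sorted nm), `indices` (band indices),
#'   `type` (peak/valley), `source` and `prominence_frac`.
#' @export
pc3_feature_wavelengths <- function(model, prominence_frac = 0.10,
                                    component = 3L, flat_eps = 1e-8) {
  stopifnot(inherits(model, "pca_model"))
  if (model$k < component) {
    stop(sprintf("model has %d components; need at least %d", model$k,
                 component), call. = FALSE)
  }
  load3 <- model$loadings[, component]
  rng <- max(load3) - min(load3)
  if (rng < flat_eps) {
    warning("loading curve is flat; no feature wavelengths", call. = FALSE)
    return(list(wavelengths = numeric(), indices = integer(),
                type = character(), source = "pc3_loading",
                prominence_frac = prominence_frac))
  }
  ex <- find_extrema(load3, min_prominence = prominence_frac * rng)
  ord <- order(ex$index)
  list(wavelengths = model$wavelengths[ex$index[ord]],
       indices = ex$index[ord], type = ex$type[ord],
       source = "pc3_loading", prominence_frac = prominence_frac)
}
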