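# ANOVA two-band ratio route: exhaustively score every ordered band pair
# (i, j) by the one-way ANOVA F statistic of the per-seed reflectance
# ratio lambda_i / lambda_j across harvest-year classes, pick the pair with
# the largest F, and classify seeds by comparing that single ratio against
# two learned cut values.

#' One-way ANOVA F statistic
#'
#' Classical equal-variance one-way F: between-group mean square over
#' within-group mean square. If the within-group variance is zero the
#' statistic is `Inf` when group means differ and 0 (with a warning) when
#' all values are identical.
#'
#' @param groups List of numeric vectors, one per group; at least 2 groups
#'   with at least 2 observations each.
#' @return The F statistic (possibly `Inf`).
#' @export
anova_f <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs at least 2 observations",
                            call. = FALSE)
  k <- length(groups)
  n <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(sizes * means) / n
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(g) sum((groups[[g]] - means[g])^2),
                          numeric(1)))
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (n - k)
  if (ms_within == 0) {
    if (ss_between > 0) return(Inf)
    warning("all values identical; F defined as 0", call. = FALSE)
    return(0)
  }
  ms_between / ms_within
}

#' Exhaustive ANOVA F search over all two-band ratios
#'
#' For every ordered band pair `(i, j)`, `i != j`, computes the per-seed
#' ratio `x_i / x_j` from the mean spectra and its one-way F across
#' classes. Ordered pairs matter: the reciprocal is a nonlinear transform,
#' so `F[i, j]` generally differs from `F[j, i]`, and on real seeds the
#' high-nm band can land in the numerator for one seed face and the
#' denominator for the other. Bands with any zero reflectance are excluded
#' as denominators.
#'
#' @param x A [spectra_table] (with class labels) or seeds x bands matrix.
#' @param labels Class labels (taken from the table when omitted).
#' @param wavelengths Band grid (taken from the table when omitted).
#' @return A `band_ratio_search` with `f_matrix` (bands x bands,
#'   numerator x denominator, `NA` on the diagonal and for invalid pairs),
#'   `best_pair` (named nm vector), `best_idx`, `best_f` and
#'   `ratios_by_class` at the best pair.
#' @export
search_ratios <- function(x, labels = NULL, wavelengths = NULL) {
  if (inherits(x, "spectra_table")) {
    labels <- labels %||% x$class
    wavelengths <- wavelengths %||% x$wavelengths
    x <- x$reflectance
  }
  stopifnot(is.matrix(x), !is.null(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2L)) stop("each class needs at least 2 seeds",
                                    call. = FALSE)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 bands", call. = FALSE)
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  n <- nrow(x)
  k <- nlevels(labels)
  sizes <- as.vector(table(labels))
  bad_den <- apply(x == 0, 2L, any)
  fmat <- matrix(NA_real_, p, p)
  gidx <- as.integer(labels)
  for (i in seq_len(p)) {
    r <- x[, i] / x                      # n x p: ratios lambda_i / lambda_j
    gs <- rowsum(r, gidx)                # k x p group sums
    gm <- gs / sizes
    grand <- colSums(gs) / n
    ss_between <- colSums(sizes * (gm - matrix(grand, k, p, byrow = TRUE))^2)
    ss_total <- colSums(r^2) - n * grand^2
    ss_within <- pmax(ss_total - ss_between, 0)
    f <- (ss_between / (k - 1)) / (ss_within / (n - k))
    f[ss_within == 0 & ss_between > 0] <- Inf
    f[ss_within == 0 & ss_between <= 0] <- 0
    f[bad_den] <- NA_real_
    f[i] <- NA_real_
    fmat[i, ] <- f
  }
  if (all(is.na(fmat))) stop("no valid band pair", call. = FALSE)
  best <- which(fmat == max(fmat, na.rm = TRUE), arr.ind = TRUE)
  # ties: lower numerator nm, then lower denominator nm (grid is ascending)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  ratios <- x[, best[1L]] / x[, best[2L]]
  structure(list(f_matrix = fmat,
                 wavelengths = as.numeric(wavelengths),
                 best_idx = c(num = unname(best[1L]), den = unname(best[2L])),
                 best_pair = c(num_nm = wavelengths[best[1L]],
                               den_nm = wavelengths[best[2L]]),
                 best_f = fmat[best[1L], best[2L]],
                 ratios_by_class = split(ratios, labels)),
            class = "band_ratio_search")
}

#' @export
print.band_ratio_search <- function(x, ...) {
  cat(sprintf("<band_ratio_search> best ratio %.1f nm / %.1f nm, F = %.1f\n",
              x$best_pair[["num_nm"]], x$best_pair[["den_nm"]], x$best_f))
  invisible(x)
}

#' Write the F-value matrix as CSV
#'
#' @param search A `band_ratio_search`.
#' @param path CSV path; rows are numerator bands, columns denominators.
#' @return Invisibly, `path`.
#' @export
write_f_matrix_csv <- function(search, path) {
  m <- search$f_matrix
  dimnames(m) <- list(sprintf("num_%.2f", search$wavelengths),
                      sprintf("den_%.2f", search$wavelengths))
  utils::write.csv(m, path)
  invisible(path)
}

#' Fit the two-threshold ratio classifier
#'
#' Orders the classes by their mean calibration ratio, considers every
#' midpoint between consecutive sorted calibration ratios as a candidate
#' cut, and picks the cut pair `(t1, t2)`, `t1 < t2`, that maximises
#' calibration accuracy under the rule of [predict_thresholds()]. Ties are
#' broken by the larger worst-case margin (half-gap around each cut), then
#' by the smaller `(t1, t2)`. With two classes a single cut `t1` is fitted.
#'
#' @param ratios Numeric vector of per-seed band ratios (calibration set).
#' @param labels Class labels, exactly 3 classes (or 2 for the binary
#'   variant).
#' @return A `threshold_model` with `t1`, `t2` (`NA` for binary),
#'   `class_order` (labels sorted by mean ratio), `accuracy` (maximised
#'   calibration accuracy, fraction) and `band_pair` (filled by callers).
#' @export
fit_thresholds <- function(ratios, labels) {
  stopifnot(is.numeric(ratios), length(ratios) == length(labels))
  if (any(!is.finite(ratios))) stop("ratios must be finite", call. = FALSE)
  labels <- factor(labels)
  k <- nlevels(labels)
  if (!k %in% c(2L, 3L)) {
    stop("fit_thresholds expects 2 or 3 classes", call. = FALSE)
  }
  if (length(unique(ratios)) < k) {
    stop("fewer distinct ratio values than classes", call. = FALSE)
  }
  class_means <- tapply(ratios, labels, mean)
  class_order <- levels(labels)[order(class_means)]
  sr <- sort(unique(ratios))
  cuts <- (sr[-length(sr)] + sr[-1L]) / 2
  margins <- diff(sr) / 2
  m <- length(cuts)
  # cumulative per-class counts at or below each cut
  n_le <- vapply(class_order, function(cl) {
    vapply(cuts, function(t) sum(ratios[labels == cl] <= t), numeric(1))
  }, numeric(m))                      # m x k
  if (k == 2L) {
    n2 <- sum(labels == class_order[2L])
    correct <- n_le[, 1L] + (n2 - n_le[, 2L])
    best <- which(correct == max(correct))
    best <- best[order(-margins[best], cuts[best])][1L]
    model <- list(t1 = cuts[best], t2 = NA_real_, class_order = class_order,
                  accuracy = max(correct) / length(ratios),
                  band_pair = NULL)
  } else {
    n3 <- sum(labels == class_order[3L])
    f_i <- n_le[, 1L] - n_le[, 2L]
    g_j <- n_le[, 2L] - n_le[, 3L]
    correct <- outer(f_i, g_j, "+") + n3          # [i, j] for t1 = cuts[i], t2 = cuts[j]
    correct[!upper.tri(correct)] <- -Inf           # enforce t1 < t2
    maxc <- max(correct)
    cand <- which(correct == maxc, arr.ind = TRUE)
    pm <- pmin(margins[cand[, 1L]], margins[cand[, 2L]])
    cand <- cand[order(-pm, cuts[cand[, 1L]], cuts[cand[, 2L]]), ,
                 drop = FALSE][1L, ]
    model <- list(t1 = cuts[cand[1L]], t2 = cuts[cand[2L]],
                  class_order = class_order,
                  accuracy = maxc / length(ratios), band_pair = NULL)
  }
  structure(model, class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> t1 = %.4f%s; classes (low to high ratio): %s; calibration accuracy %.2f%%\n",
              x$t1, if (is.na(x$t2)) "" else sprintf(", t2 = %.4f", x$t2),
              paste(x$class_order, collapse = " < "), 100 * x$accuracy))
  invisible(x)
}

#' Classify seeds from their band ratio with a fitted threshold model
#'
#' Rule (boundary belongs to the left): `r <= t1` gives the lowest-ratio
#' class, `t1 < r <= t2` the middle class, `r > t2` the highest. Non-finite
#' ratios yield `NA` with a warning.
#'
#' @param model A `threshold_model`.
#' @param ratios Numeric vector of band ratios.
#' @return Factor of predicted class labels (levels = `class_order`).
#' @export
predict_thresholds <- function(model, ratios) {
  stopifnot(inherits(model, "threshold_model"))
  out <- rep(NA_character_, length(ratios))
  ok <- is.finite(ratios)
  if (any(!ok)) warning(sprintf("%d non-finite ratio(s) left unclassified",
                                sum(!ok)), call. = FALSE)
  if (is.na(model$t2)) {
    out[ok] <- ifelse(ratios[ok] <= model$t1, model$class_order[1L],
                      model$class_order[2L])
  } else {
    out[ok] <- ifelse(ratios[ok] <= model$t1, model$class_order[1L],
                      ifelse(ratios[ok] <= model$t2, model$class_order[2L],
                             model$class_order[3L]))
  }
  factor(out, levels = model$class_order)
}

#' Serialize a threshold model to JSON
#'
#' @param model A `threshold_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_threshold_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
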