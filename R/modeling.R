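# Supervised classification: RBF-kernel SVMs tuned by grid search over
# cost and gamma (powers of two spanning 2^-10..2^10) with stratified
# five-fold cross-validation on the calibration set, then refit on the full
# calibration set. Multiclass handling is libSVM's one-vs-one voting.

#' Stratified random calibration/prediction split
#'
#' Draws `n_cal` calibration seeds stratified by class (largest-remainder
#' apportionment of the per-class quotas), deterministically for a given
#' seed. At the study scale, 240 of 360 seeds are calibration (80 per
#' class) and the remaining 120 are the prediction set.
#'
#' @param labels Class label per seed.
#' @param n_cal Total calibration-set size, `< length(labels)`.
#' @param rng_seed Integer seed.
#' @return Character vector of `"calibration"` / `"prediction"` tags.
#' @export
split_calibration <- function(labels, n_cal, rng_seed = 1L) {
  labels <- factor(labels)
  n <- length(labels)
  if (n_cal >= n) stop("n_cal must be smaller than the number of seeds",
                       call. = FALSE)
  if (n_cal < nlevels(labels)) stop("n_cal smaller than the number of classes",
                                    call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 seeds",
                             call. = FALSE)
  quota <- n_cal * as.vector(counts) / n
  take <- floor(quota)
  rem <- n_cal - sum(take)
  if (rem > 0L) {
    extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  tags <- rep("prediction", n)
  withr::with_seed(rng_seed, {
    for (k in seq_len(nlevels(labels))) {
      idx <- which(as.integer(labels) == k)
      tags[sample(idx, take[k])] <- "calibration"
    }
  })
  tags
}

#' RBF-SVM tuning specification
#'
#' @param cost_grid,gamma_grid Candidate values; defaults are the 21
#'   integer powers of two from `2^-10` to `2^10`.
#' @param folds Number of cross-validation folds (default 5).
#' @param rng_seed Seed for the stratified fold assignment.
#' @return An `svm_spec` list.
#' @export
svm_spec <- function(cost_grid = 2^(-10:10), gamma_grid = 2^(-10:10),
                     folds = 5L, rng_seed = 1L) {
  stopifnot(all(cost_grid > 0), all(gamma_grid > 0), folds >= 2L)
  structure(list(cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
                 folds = as.integer(folds), rng_seed = as.integer(rng_seed)),
            class = "svm_spec")
}

# Stratified fold ids: within each class, shuffle then deal round-robin.
stratified_folds <- function(y, folds, rng_seed) {
  fold <- integer(length(y))
  withr::with_seed(rng_seed, {
    for (k in levels(y)) {
      idx <- sample(which(y == k))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Train an RBF-SVM with grid-searched cost and gamma
#'
#' Every `(cost, gamma)` combination is scored by pooled stratified
#' `folds`-fold cross-validation accuracy on the calibration rows; ties go
#' to the smallest cost, then the smallest gamma. The winning combination
#' is refit on all calibration rows. Features are used as provided (no
#' internal rescaling), so any normalization must be done beforehand with
#' calibration-set statistics.
#'
#' @param x Numeric feature matrix (calibration rows only).
#' @param y Class label per row.
#' @param spec An [svm_spec()].
#' @return A `seed_svm` with the fitted `e1071::svm` model, `cost`,
#'   `gamma`, `cv_accuracy` (fraction) and the full `grid` of CV
#'   accuracies.
#' @export
train_svm <- function(x, y, spec = svm_spec()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes to train", call. = FALSE)
  fold <- stratified_folds(y, spec$folds, spec$rng_seed)
  grid <- expand.grid(gamma = spec$gamma_grid, cost = spec$cost_grid)
  grid <- grid[order(grid$cost, grid$gamma), ]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(spec$folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2L) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc)                     # first max: smallest cost, gamma
  fit <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE)
  structure(list(fit = fit, cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best], levels = levels(y),
                 grid = cbind(grid, cv_accuracy = acc)),
            class = "seed_svm")
}

#' @export
print.seed_svm <- function(x, ...) {
  cat(sprintf("<seed_svm> RBF, cost = %g, gamma = %g, CV accuracy %.2f%%\n",
              x$cost, x$gamma, 100 * x$cv_accuracy))
  invisible(x)
}

#' @export
predict.seed_svm <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata)
}

#' Accuracy and confusion matrix of predictions
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @return A `classification_report` with `accuracy` (percent),
#'   `confusion` (rows = truth, columns = predicted) and `n`.
#' @export
report_classification <- function(pred, truth) {
  truth <- factor(truth)
  pred_chr <- as.character(pred)
  unseen <- setdiff(stats::na.omit(unique(pred_chr)), levels(truth))
  if (length(unseen) > 0L) {
    stop("prediction contains class label(s) unseen in the truth: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  pred <- factor(pred_chr, levels = levels(truth))
  cm <- table(truth = truth, predicted = pred)
  structure(list(accuracy = 100 * sum(diag(cm)) / length(truth),
                 confusion = cm, n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% (n = %d)\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted classifier on calibration and prediction rows
#'
#' @param model A `seed_svm` or `threshold_model`.
#' @param x Feature matrix (SVM) or ratio vector (threshold model) for all
#'   seeds.
#' @param y True labels for all seeds.
#' @param split Tags from [split_calibration()].
#' @return List with `calibration` and `prediction`
#'   `classification_report`s.
#' @export
evaluate <- function(model, x, y, split) {
  pred <- if (inherits(model, "threshold_model")) {
    predict_thresholds(model, x)
  } else {
    predict(model, x)
  }
  cal <- split == "calibration"
  list(calibration = report_classification(pred[cal], y[cal]),
       prediction = report_classification(pred[!cal], y[!cal]))
}

#' Collapse harvest-year labels to new vs aged
#'
#' The most recent harvest year is "new"; every earlier year is "aged".
#'
#' @param labels Class labels (coercible to integer years).
#' @param new_class The label counting as new (default: the numeric
#'   maximum).
#' @return Factor with levels `c("aged", "new")`.
#' @export
collapse_binary <- function(labels, new_class = NULL) {
  lab <- as.character(labels)
  if (is.null(new_class)) {
    years <- suppressWarnings(as.numeric(unique(lab)))
    if (anyNA(years)) stop("cannot infer the newest class; give `new_class`",
                           call. = FALSE)
    new_class <- unique(lab)[which.max(years)]
  }
  factor(ifelse(lab == as.character(new_class), "new", "aged"),
         levels = c("aged", "new"))
}
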