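# End-to-end orchestration: generate (or ingest) plates, calibrate, crop,
# segment, extract per-seed spectra for both seed faces, then fit and
# evaluate every feature representation on one shared calibration /
# prediction split: full spectra, first three PCs, PC3-loading feature
# wavelengths, the ANOVA-selected two-band ratio (threshold rule and
# 1-variable SVM), the 10 ratio-image textures, and the 11-variable
# ratio + texture fusion, plus the binary new-vs-aged collapse.

#' Pipeline configuration
#'
#' @param n_per_class Seeds per harvest-year class (study scale: 120).
#' @param seeds_per_plate Seeds imaged per plate (study scale: 60; plates
#'   hold seeds of a single class).
#' @param classes List of [spectral_class_spec()]s.
#' @param image_height,image_width Scene size in pixels.
#' @param seed_axes Seed semi-axis ranges, see [scene_spec()].
#' @param crop Working wavelength window in nm.
#' @param mask_nm Masking band for segmentation.
#' @param min_area Minimum seed area in pixels.
#' @param L Gray levels for texture quantization.
#' @param cal_frac Fraction of seeds in the calibration set (2/3, i.e.
#'   240/360 at study scale).
#' @param svm An [svm_spec()].
#' @param sp [side_params()] of the generator.
#' @param data_seed Master seed for scene generation.
#' @param split_seed Seed of the calibration/prediction split.
#' @param verbose Emit progress messages.
#' @param audit_permute_prediction Internal audit switch: randomly permute
#'   the prediction-set labels before any fitting. Model parameters must
#'   not change (nothing is fit on prediction rows); only the reported
#'   prediction accuracies become meaningless.
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(n_per_class = 120L, seeds_per_plate = 60L,
                            classes = default_class_specs(),
                            image_height = 256L, image_width = 320L,
                            seed_axes = list(major = c(8, 12), minor = c(6, 9)),
                            crop = c(1000, 2000), mask_nm = 1098,
                            min_area = 30L, L = 64L, cal_frac = 2 / 3,
                            svm = svm_spec(), sp = side_params(),
                            data_seed = 42L, split_seed = 7L,
                            verbose = FALSE,
                            audit_permute_prediction = FALSE) {
  cfg <- as.list(environment())
  if (length(cfg$classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] can be overridden from a YAML
#' file; unknown keys are rejected.
#'
#' @param path YAML path.
#' @return A config list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) stop("unknown config key(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# Generate all plates for both sides and extract per-seed spectra plus the
# per-seed pixel stores needed for ratio-image textures.
acquire_sides <- function(cfg) {
  K <- length(cfg$classes)
  plate_seeds <- derive_seeds(cfg$data_seed, K * 64L)
  sides <- list(embryo = NULL, endosperm = NULL)
  store <- list(embryo = list(), endosperm = list())
  refl <- list(embryo = NULL, endosperm = NULL)
  labels <- integer(0)
  plate_i <- 0L
  for (k in seq_len(K)) {
    left <- cfg$n_per_class
    while (left > 0L) {
      m <- min(cfg$seeds_per_plate, left)
      left <- left - m
      plate_i <- plate_i + 1L
      sc <- scene_spec(image_height = cfg$image_height,
                       image_width = cfg$image_width,
                       seeds_per_plate = m, seed_axes = cfg$seed_axes,
                       rng_seed = plate_seeds[plate_i])
      if (cfg$verbose) message(sprintf("plate %d: class %d, %d seeds",
                                       plate_i, cfg$classes[[k]]$class_id, m))
      pair <- stage("generate", paired_sides(sc, cfg$classes[k],
                                             labels = rep(1L, m), sp = cfg$sp))
      plate_labels <- NULL
      for (side in c("embryo", "endosperm")) {
        bundle <- pair[[side]]
        cube <- stage("calibrate",
                      calibrate(bundle$raw, bundle$white, bundle$dark))
        cube <- stage("crop", crop_bands(cube, cfg$crop[1L], cfg$crop[2L]))
        mask <- stage("mask", build_mask(cube, mask_nm = cfg$mask_nm,
                                         min_area = cfg$min_area))
        regions <- stage("split", split_seeds(mask, min_area = cfg$min_area))
        if (length(regions) != m) {
          stop(sprintf("stage split: found %d regions, expected %d seeds",
                       length(regions), m), call. = FALSE)
        }
        lab <- stage("label", assign_labels(regions, bundle$truth,
                                            dim(cube)[1:2]))
        if (side == "embryo") plate_labels <- lab
        refl[[side]] <- rbind(refl[[side]],
                              t(vapply(regions,
                                       function(r) mean_spectrum(cube, r),
                                       numeric(length(cube$wavelengths)))))
        store[[side]] <- c(store[[side]],
                           lapply(regions,
                                  function(r) seed_pixel_values(cube, r)))
        sides$wavelengths <- cube$wavelengths
      }
      labels <- c(labels, plate_labels)
    }
  }
  n <- length(labels)
  list(
    embryo = spectra_table(refl$embryo, sides$wavelengths, class = labels,
                           side = "embryo", seed_id = seq_len(n)),
    endosperm = spectra_table(refl$endosperm, sides$wavelengths,
                              class = labels, side = "endosperm",
                              seed_id = seq_len(n)),
    pixels = store, labels = labels, wavelengths = sides$wavelengths)
}

svm_report <- function(x, y, split, cfg, side, representation) {
  cal <- split == "calibration"
  model <- stage(paste0("svm_", representation),
                 train_svm(x[cal, , drop = FALSE], y[cal], spec = cfg$svm))
  ev <- evaluate(model, x, y, split)
  list(side = side, representation = representation, n_vars = ncol(x),
       params = c(cost = model$cost, gamma = model$gamma),
       cv_accuracy = 100 * model$cv_accuracy,
       calibration_accuracy = ev$calibration$accuracy,
       prediction_accuracy = ev$prediction$accuracy,
       confusion_calibration = ev$calibration$confusion,
       confusion_prediction = ev$prediction$confusion)
}

#' Run the full classification pipeline on synthetic plates
#'
#' Produces one `classification_report`-style entry per side and feature
#' representation (18 in total: full spectra, first-3 PCs, PC3-loading
#' wavelengths and ratio-threshold for embryo, endosperm and both sides;
#' 1-variable ratio SVM, 10-variable textures and 11-variable fusion for
#' the two imaged faces), plus the binary new-vs-aged fusion model, on one
#' shared stratified calibration/prediction split. Every model parameter
#' -- PCA centring and loadings, feature wavelengths, best band pair,
#' thresholds, texture quantizer and scaler, SVM hyperparameters -- is fit
#' on calibration rows only.
#'
#' @param cfg A [pipeline_config()] (or a YAML path readable by
#'   [read_pipeline_config()]).
#' @return A `seedage_pipeline` list: `reports` (18 entries),
#'   `binary` (binary-task report), `artifacts` (fitted parameters per
#'   side), `split`, `labels`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!is.list(cfg) || is.null(cfg$n_per_class)) {
    stop("invalid pipeline config", call. = FALSE)
  }
  acq <- acquire_sides(cfg)
  n <- length(acq$labels)
  y <- factor(acq$labels)
  split <- split_calibration(y, n_cal = round(cfg$cal_frac * n),
                             rng_seed = cfg$split_seed)
  if (isTRUE(cfg$audit_permute_prediction)) {
    pr <- which(split == "prediction")
    y[pr] <- withr::with_seed(cfg$split_seed + 1L, sample(y[pr]))
  }
  cal <- split == "calibration"
  tables <- list(embryo = acq$embryo, endosperm = acq$endosperm,
                 both = pair_and_average(acq$embryo, acq$endosperm))
  reports <- list()
  artifacts <- list()
  for (side in names(tables)) {
    tb <- tables[[side]]
    x_full <- tb$reflectance
    if (cfg$verbose) message("modelling side: ", side)
    reports[[paste0(side, "_full")]] <-
      svm_report(x_full, y, split, cfg, side, "full")

    pca <- stage("pca", fit_pca(x_full[cal, , drop = FALSE], k = 3,
                                wavelengths = tb$wavelengths))
    scores <- project(pca, x_full)
    reports[[paste0(side, "_pcs")]] <-
      svm_report(scores, y, split, cfg, side, "pcs")

    fw <- stage("pc3_features", pc3_feature_wavelengths(pca))
    if (length(fw$indices) == 0L) {
      stop("stage pc3_features: flat PC3 loading, no feature wavelengths",
           call. = FALSE)
    }
    reports[[paste0(side, "_loading")]] <-
      svm_report(x_full[, fw$indices, drop = FALSE], y, split, cfg, side,
                 "loading_wavelengths")

    sr <- stage("bandratio", search_ratios(x_full[cal, , drop = FALSE],
                                           labels = y[cal],
                                           wavelengths = tb$wavelengths))
    ratios <- x_full[, sr$best_idx[["num"]]] / x_full[, sr$best_idx[["den"]]]
    thr <- stage("thresholds", fit_thresholds(ratios[cal], y[cal]))
    thr$band_pair <- sr$best_pair
    ev <- evaluate(thr, ratios, y, split)
    reports[[paste0(side, "_ratio_threshold")]] <- list(
      side = side, representation = "ratio_threshold", n_vars = 1L,
      params = c(t1 = thr$t1, t2 = thr$t2),
      calibration_accuracy = ev$calibration$accuracy,
      prediction_accuracy = ev$prediction$accuracy,
      confusion_calibration = ev$calibration$confusion,
      confusion_prediction = ev$prediction$confusion)

    artifacts[[side]] <- list(
      pca_evr = pca$explained_variance_ratio,
      pca_center = pca$center, pca_loadings = pca$loadings,
      feature_wavelengths = fw$wavelengths,
      best_pair = sr$best_pair, best_idx = sr$best_idx, best_f = sr$best_f,
      t1 = thr$t1, t2 = thr$t2,
      threshold_cal_accuracy = 100 * thr$accuracy)

    if (side %in% c("embryo", "endosperm")) {
      reports[[paste0(side, "_ratio_svm")]] <-
        svm_report(matrix(ratios, ncol = 1L,
                          dimnames = list(NULL, "ratio")),
                   y, split, cfg, side, "ratio")

      imgs <- lapply(acq$pixels[[side]], ratio_image,
                     num = sr$best_idx[["num"]], den = sr$best_idx[["den"]])
      qz <- stage("quantizer",
                  make_quantizer(unlist(lapply(imgs[cal], function(im)
                    im[!is.na(im)])), L = cfg$L))
      tex <- t(vapply(imgs, texture_vector, numeric(10), q = qz))
      nrm <- stage("normalize", normalize_features(tex, cal))
      reports[[paste0(side, "_textures")]] <-
        svm_report(nrm$x, y, split, cfg, side, "textures")

      # the ratio column is standardized with calibration statistics like
      # the textures: an RBF kernel would otherwise ignore a feature whose
      # spread (~0.03 ratio units) is tiny next to unit-variance textures
      rn <- normalize_features(matrix(ratios, ncol = 1L,
                                      dimnames = list(NULL, "ratio")), cal)
      fusion <- cbind(rn$x, nrm$x)
      reports[[paste0(side, "_fusion")]] <-
        svm_report(fusion, y, split, cfg, side, "fusion")

      artifacts[[side]]$quantizer <- qz
      artifacts[[side]]$texture_center <- nrm$center
      artifacts[[side]]$texture_scale <- nrm$scale
      artifacts[[side]]$ratio_center <- rn$center
      artifacts[[side]]$ratio_scale <- rn$scale
      if (side == "embryo") {
        emb_fusion <- fusion
      }
    }
  }
  y_bin <- collapse_binary(y)
  binary <- svm_report(emb_fusion, y_bin, split, cfg, "embryo",
                       "fusion_binary")
  structure(list(reports = reports, binary = binary, artifacts = artifacts,
                 split = split, labels = y, config = cfg),
            class = "seedage_pipeline")
}

#' @export
print.seedage_pipeline <- function(x, ...) {
  cat(sprintf("<seedage_pipeline> %d seeds, %d reports\n",
              length(x$labels), length(x$reports)))
  df <- do.call(rbind, lapply(x$reports, function(r)
    data.frame(side = r$side, representation = r$representation,
               n_vars = r$n_vars,
               calibration = sprintf("%.2f", r$calibration_accuracy),
               prediction = sprintf("%.2f", r$prediction_accuracy))))
  rownames(df) <- NULL
  print(df)
  cat(sprintf("binary (new vs aged, embryo fusion): prediction %.2f%%\n",
              x$binary$prediction_accuracy))
  invisible(x)
}

#' Write pipeline reports as JSON
#'
#' @param bundle A `seedage_pipeline`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_json <- function(bundle, path) {
  strip <- function(r) {
    r$confusion_calibration <- as.data.frame(r$confusion_calibration)
    r$confusion_prediction <- as.data.frame(r$confusion_prediction)
    r
  }
  obj <- list(reports = lapply(bundle$reports, strip),
              binary = strip(bundle$binary),
              artifacts = lapply(bundle$artifacts, function(a) {
                a$pca_loadings <- NULL   # bulky; persisted separately if needed
                a$pca_center <- NULL
                a
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
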