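# Synthetic hyperspectral scene generator. Produces raw NIR cubes of maize
# seed plates together with the white/dark reference frames and a full
# ground truth (per-seed masks, class labels, noise-free mean spectra), so
# that every downstream stage of the pipeline can be exercised and verified
# without any imaging hardware.
#
# The sensor model is affine: raw = dark + (white - dark) * reflectance +
# noise, with noise expressed as a reflectance-domain standard deviation, so
# that standard flat-field calibration recovers the true reflectance in
# expectation (and exactly, when all noise terms are zero).

#' Default instrument wavelength grid
#'
#' 258 bands from 930 nm at a 6.29 nm spacing (up to ~2547 nm), emulating a
#' line-scan NIR spectrograph. Exactly 159 of these bands fall in the
#' working window 1000-2000 nm that the analysis retains.
#'
#' @return Numeric vector of band centres in nm.
#' @export
default_wavelengths <- function() seq(930, by = 6.29, length.out = 258)

#' Spectral description of one harvest-year class
#'
#' The class mean reflectance curve is a baseline level plus a set of
#' Gaussian absorption/reflection features plus extra offsets at the
#' spectral extremes. The extreme offsets emulate the observation that
#' harvest years differ most below ~1100 nm and, especially, above ~1400 nm,
#' which is what makes two-band ratios taken near the ends of the range
#' discriminative.
#'
#' @param class_id Integer class identifier (use the harvest year).
#' @param baseline_offset Baseline reflectance level (unitless, in `[0,1]`).
#' @param feature_bands List of numeric triples `c(centre_nm, width_nm,
#'   amplitude)` added as Gaussian bumps (positive amplitude) or dips
#'   (negative).
#' @param extreme_separation Numeric pair `c(low, high)`: extra reflectance
#'   added below the low-nm pivot (1100 nm) and above the high-nm pivot
#'   (1400 nm), with smooth logistic ramps.
#' @param noise_sd Per-band reflectance noise SD. Applied twice: as the SD
#'   of a spectrally smooth per-seed deviation curve (kernel-to-kernel
#'   spectral variability; correlation length `noise_corr_bands`), and as
#'   the SD of independent per-pixel noise within the seed.
#' @param seed_offset_sd SD of the flat per-seed reflectance offset that
#'   models kernel-to-kernel variability.
#' @param noise_corr_bands Correlation length (in bands) of the per-seed
#'   spectral deviation; reflectance spectra averaged over hundreds of
#'   pixels vary smoothly with wavelength, not band-by-band. Set 0 for
#'   independent per-band noise.
#' @param embryo_contrast Optional class-specific reflectance offset of the
#'   embryo patch on embryo-side scenes, overriding the scene-wide value in
#'   [side_params()]. Seed aging alters the germ, so the embryo/endosperm
#'   contrast -- and with it the ratio-image texture -- is class dependent.
#' @param pixel_noise_sd Reflectance SD of the independent per-pixel noise
#'   inside the seed (defaults to `noise_sd`). Tissue degradation makes
#'   aged kernels more heterogeneous, so the within-seed graininess -- the
#'   main driver of the spread- and co-occurrence-type texture features --
#'   is class dependent in the default specs.
#' @return A `spectral_class_spec` object.
#' @export
spectral_class_spec <- function(class_id, baseline_offset,
                                feature_bands = default_feature_bands(),
                                extreme_separation = c(0, 0),
                                noise_sd = 0.01,
                                seed_offset_sd = 0.01,
                                noise_corr_bands = 3,
                                embryo_contrast = NULL,
                                pixel_noise_sd = NULL) {
  stopifnot(length(extreme_separation) == 2L, noise_sd >= 0,
            seed_offset_sd >= 0, baseline_offset >= 0, baseline_offset <= 1,
            noise_corr_bands >= 0)
  structure(list(class_id = as.integer(class_id),
                 baseline_offset = baseline_offset,
                 feature_bands = feature_bands,
                 extreme_separation = as.numeric(extreme_separation),
                 noise_sd = noise_sd,
                 seed_offset_sd = seed_offset_sd,
                 noise_corr_bands = noise_corr_bands,
                 embryo_contrast = embryo_contrast,
                 pixel_noise_sd = pixel_noise_sd %||% noise_sd),
            class = "spectral_class_spec")
}

# Zero-mean noise curve with per-band marginal SD `sd` and a Gaussian
# band-to-band correlation of length `corr` bands (iid when corr == 0).
smooth_noise <- function(nb, sd, corr) {
  if (sd == 0) return(numeric(nb))
  if (corr <= 0) return(stats::rnorm(nb, 0, sd))
  half <- ceiling(3 * corr)
  k <- stats::dnorm(seq(-half, half), sd = corr)
  k <- k / sqrt(sum(k^2))           # unit marginal variance after filtering
  e <- stats::rnorm(nb + 2L * half)
  sd * as.numeric(stats::filter(e, k, sides = 2))[(half + 1L):(half + nb)]
}

#' @rdname spectral_class_spec
#' @export
default_feature_bands <- function() {
  list(c(1110, 45,  0.06),   # carbohydrate C-H overtone peak
       c(1200, 40, -0.05),   # C-H valley
       c(1300, 50,  0.05),   # amide-related peak
       c(1467, 60, -0.07))   # protein N-H valley
}

#' Default three-class (harvest year) spectral specs
#'
#' Three classes labelled 2018, 2019, 2020. Reflectance increases with
#' storage time (2018 brightest), the mid-range curves overlap
#' substantially, and the separation grows toward both spectral extremes,
#' strongest above 1400 nm. The embryo-patch contrast deepens with seed
#' age, so embryo-side ratio-image textures carry class information of
#' their own.
#'
#' @param noise_sd Per-band reflectance noise SD shared by all classes.
#' @return List of three [spectral_class_spec] objects.
#' @export
default_class_specs <- function(noise_sd = 0.01) {
  list(
    spectral_class_spec(2018L, 0.46, extreme_separation = c(0.020, 0.060),
                        noise_sd = noise_sd, embryo_contrast = -0.065,
                        pixel_noise_sd = 0.013),
    spectral_class_spec(2019L, 0.43, extreme_separation = c(0.010, 0.030),
                        noise_sd = noise_sd, embryo_contrast = -0.050,
                        pixel_noise_sd = 0.010),
    spectral_class_spec(2020L, 0.40, extreme_separation = c(0.000, 0.000),
                        noise_sd = noise_sd, embryo_contrast = -0.035,
                        pixel_noise_sd = 0.007)
  )
}

#' Class mean reflectance curve on a wavelength grid
#'
#' @param spec A [spectral_class_spec].
#' @param wavelengths Numeric nm vector.
#' @param lo_pivot,hi_pivot Pivots (nm) below/above which the extreme
#'   separation offsets apply.
#' @param ramp Logistic ramp scale in nm.
#' @return Numeric reflectance vector in `[0, 1]`.
#' @export
class_mean_spectrum <- function(spec, wavelengths, lo_pivot = 1100,
                                hi_pivot = 1400, ramp = 30) {
  check_wavelengths(wavelengths)
  r <- rep(spec$baseline_offset, length(wavelengths))
  for (fb in spec$feature_bands) {
    r <- r + fb[3L] * exp(-((wavelengths - fb[1L]) / fb[2L])^2)
  }
  r <- r + spec$extreme_separation[1L] * stats::plogis((lo_pivot - wavelengths) / ramp)
  r <- r + spec$extreme_separation[2L] * stats::plogis((wavelengths - hi_pivot) / ramp)
  if (any(r < 0 | r > 1)) {
    stop("class mean reflectance leaves [0, 1]; adjust the class spec",
         call. = FALSE)
  }
  r
}

#' Scene geometry and acquisition parameters
#'
#' @param image_height,image_width Scene size in pixels (along-scan x
#'   cross-track). Defaults match a 256 x 320 line-scan camera frame.
#' @param seeds_per_plate Number of seeds on the plate (default 60).
#' @param seed_axes List with `major` and `minor` semi-axis pixel ranges for
#'   the elliptical seeds.
#' @param background_level Mean raw counts of the dark background plate.
#' @param white_level,dark_level Mean raw counts of the white reference and
#'   the dark (shutter-closed) reference.
#' @param ref_noise_sd Count-domain noise SD of the reference frames.
#' @param background_noise_sd Reflectance-domain pixel noise SD of the
#'   background.
#' @param wavelength_grid Band centres in nm ([default_wavelengths()]).
#' @param rng_seed Integer seed; all randomness in scene generation flows
#'   from it.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(image_height = 256L, image_width = 320L,
                       seeds_per_plate = 60L,
                       seed_axes = list(major = c(8, 12), minor = c(6, 9)),
                       background_level = 550, white_level = 9000,
                       dark_level = 100, ref_noise_sd = 2,
                       background_noise_sd = 0.005,
                       wavelength_grid = default_wavelengths(),
                       rng_seed = 1L) {
  check_wavelengths(wavelength_grid)
  stopifnot(image_height > 0, image_width > 0, seeds_per_plate >= 1,
            white_level > dark_level)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 seeds_per_plate = as.integer(seeds_per_plate),
                 seed_axes = seed_axes,
                 background_level = background_level,
                 white_level = white_level, dark_level = dark_level,
                 ref_noise_sd = ref_noise_sd,
                 background_noise_sd = background_noise_sd,
                 wavelength_grid = as.numeric(wavelength_grid),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

#' Side-dependent rendering parameters
#'
#' The embryo side of a kernel shows two compartments: an embryo (germ)
#' patch, modelled as an interior ellipse covering roughly `embryo_frac` of
#' the seed area with reflectance shifted by `embryo_contrast`, inside the
#' endosperm matrix. The endosperm side is spatially smooth and its
#' spectrum is shifted by `side_offset` relative to the embryo side's
#' endosperm compartment.
#'
#' @param side_offset Reflectance offset of the endosperm-side spectrum.
#' @param embryo_contrast Reflectance offset of the embryo patch
#'   (embryo-side scenes only).
#' @param embryo_frac Fraction of the seed area occupied by the embryo patch.
#' @return A named list.
#' @export
side_params <- function(side_offset = 0.01, embryo_contrast = -0.05,
                        embryo_frac = 1 / 3) {
  stopifnot(embryo_frac > 0, embryo_frac < 1)
  list(side_offset = side_offset, embryo_contrast = embryo_contrast,
       embryo_frac = embryo_frac)
}

# Lay seeds out on a jittered grid: one seed per cell, jitter bounded so
# that every ellipse stays inside its own cell with a 1-pixel margin.
# Guarantees disjoint masks; raises a placement error when the requested
# seed axes cannot fit the cell size implied by seeds_per_plate.
# Assumes the RNG state has been set by the caller.
make_layout <- function(scene, classes, labels = NULL) {
  n <- scene$seeds_per_plate
  if (length(classes) < 1L) stop("at least one class is required", call. = FALSE)
  if (is.null(labels)) labels <- rep_len(seq_along(classes), n)
  stopifnot(length(labels) == n, all(labels %in% seq_along(classes)))
  h <- scene$image_height; w <- scene$image_width
  nc <- ceiling(sqrt(n * w / h))
  nr <- ceiling(n / nc)
  cell_h <- floor(h / nr); cell_w <- floor(w / nc)
  a_max <- max(scene$seed_axes$major)
  if (2 * a_max + 2 > min(cell_h, cell_w)) {
    stop(sprintf(paste0("placement error: cannot fit %d seeds with semi-major ",
                        "axis up to %g px on a %d x %d plate"),
                 n, a_max, h, w), call. = FALSE)
  }
  seeds <- vector("list", n)
  for (k in seq_len(n)) {
    cell_r <- (k - 1L) %/% nc
    cell_c <- (k - 1L) %% nc
    major <- stats::runif(1, scene$seed_axes$major[1L], scene$seed_axes$major[2L])
    minor <- stats::runif(1, scene$seed_axes$minor[1L], scene$seed_axes$minor[2L])
    vertical <- stats::runif(1) < 0.5      # major axis along rows or columns
    semi_r <- if (vertical) major else minor
    semi_c <- if (vertical) minor else major
    r_lo <- cell_r * cell_h + semi_r + 1
    r_hi <- (cell_r + 1) * cell_h - semi_r - 1
    c_lo <- cell_c * cell_w + semi_c + 1
    c_hi <- (cell_c + 1) * cell_w - semi_c - 1
    if (r_hi < r_lo || c_hi < c_lo) {
      stop("placement error: seed does not fit its grid cell", call. = FALSE)
    }
    ctr <- c(stats::runif(1, r_lo, r_hi), stats::runif(1, c_lo, c_hi))
    class_spec <- classes[[labels[k]]]
    seeds[[k]] <- list(id = k, class_idx = labels[k],
                       class_id = class_spec$class_id,
                       center = ctr, semi = c(semi_r, semi_c),
                       vertical = vertical,
                       offset = stats::rnorm(1, 0, class_spec$seed_offset_sd))
  }
  seeds
}

ellipse_pixels <- function(center, semi, h, w) {
  r0 <- max(1L, floor(center[1L] - semi[1L]))
  r1 <- min(h, ceiling(center[1L] + semi[1L]))
  c0 <- max(1L, floor(center[2L] - semi[2L]))
  c1 <- min(w, ceiling(center[2L] + semi[2L]))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  d <- ((g$row - center[1L]) / semi[1L])^2 + ((g$col - center[2L]) / semi[2L])^2
  as.matrix(g[d <= 1, , drop = FALSE])
}

# Render one side of a laid-out plate. Assumes RNG state set by caller.
render_scene <- function(layout, scene, classes,
                         side = c("embryo", "endosperm"),
                         sp = side_params()) {
  side <- match.arg(side)
  h <- scene$image_height; w <- scene$image_width
  wl <- scene$wavelength_grid
  nb <- length(wl)
  npx <- h * w
  # reference frames: per cross-track column and band (line averages)
  illum <- 1 - 0.25 * ((wl - mean(range(wl))) / diff(range(wl)))^2
  vign <- 1 - 0.05 * ((seq_len(w) - (w + 1) / 2) / ((w + 1) / 2))^2
  white <- outer(vign, illum) * scene$white_level +
    matrix(stats::rnorm(w * nb, 0, scene$ref_noise_sd), w, nb)
  dark <- matrix(scene$dark_level, w, nb) +
    matrix(stats::rnorm(w * nb, 0, scene$ref_noise_sd), w, nb)

  bg_refl <- (scene$background_level - scene$dark_level) /
    (scene$white_level - scene$dark_level)
  r_true <- matrix(bg_refl, npx, nb)
  sd_px <- rep(scene$background_noise_sd, npx)

  n <- length(layout)
  masks <- vector("list", n)
  mean_spectra <- matrix(NA_real_, n, nb)
  class_ids <- integer(n)
  centroids <- matrix(NA_real_, n, 2L)
  areas <- integer(n)
  curves <- lapply(classes, class_mean_spectrum, wavelengths = wl)
  for (k in seq_len(n)) {
    s <- layout[[k]]
    px <- ellipse_pixels(s$center, s$semi, h, w)
    if (nrow(px) == 0L) stop("placement error: empty seed mask", call. = FALSE)
    lin <- px[, 1L] + (px[, 2L] - 1L) * h
    cs <- classes[[s$class_idx]]
    # the seed's true spectrum: class curve + flat offset + smooth deviation
    base <- curves[[s$class_idx]] + s$offset +
      smooth_noise(nb, cs$noise_sd, cs$noise_corr_bands)
    if (side == "endosperm") {
      spec_main <- base + sp$side_offset
      r_true[lin, ] <- matrix(spec_main, length(lin), nb, byrow = TRUE)
      mean_spectra[k, ] <- spec_main
    } else {
      # embryo patch: interior ellipse, shifted toward one end of the major
      # axis; the patch contrast may be class specific (aging alters the germ)
      contrast <- cs$embryo_contrast %||% sp$embryo_contrast
      shift <- 0.35 * s$semi * if (s$vertical) c(1, 0) else c(0, 1)
      e_px <- ellipse_pixels(s$center + shift, s$semi * sqrt(sp$embryo_frac),
                             h, w)
      e_lin <- intersect(e_px[, 1L] + (e_px[, 2L] - 1L) * h, lin)
      r_true[lin, ] <- matrix(base, length(lin), nb, byrow = TRUE)
      if (length(e_lin) > 0L) {
        r_true[e_lin, ] <- matrix(base + contrast, length(e_lin),
                                  nb, byrow = TRUE)
      }
      f <- length(e_lin) / length(lin)
      mean_spectra[k, ] <- base + f * contrast
    }
    sd_px[lin] <- cs$pixel_noise_sd
    masks[[k]] <- px
    class_ids[k] <- s$class_id
    centroids[k, ] <- colMeans(px)
    areas[k] <- nrow(px)
  }

  raw <- matrix(NA_real_, npx, nb)
  col_of_px <- rep(seq_len(w), each = h)
  any_noise <- any(sd_px > 0)
  for (b in seq_len(nb)) {
    wv <- white[col_of_px, b]
    dv <- dark[col_of_px, b]
    refl <- r_true[, b]
    if (any_noise) refl <- refl + stats::rnorm(npx, 0, sd_px)
    raw[, b] <- dv + (wv - dv) * refl
  }
  truth <- list(seed_id = seq_len(n), class_id = class_ids, side = side,
                masks = masks, centroids = centroids, areas = areas,
                mean_spectra = mean_spectra, wavelengths = wl)
  list(raw = hypercube(array(raw, c(h, w, nb)), wl, state = "raw"),
       white = white, dark = dark, truth = truth, side = side,
       scene = scene)
}

#' Generate a synthetic seed-plate scene
#'
#' Places `scene$seeds_per_plate` elliptical seeds on a jittered grid (so
#' masks are guaranteed disjoint and fully inside the image), assigns each
#' seed a harvest-year class, renders the raw hypercube under an affine
#' sensor model and returns it together with the white/dark reference
#' frames and the ground truth.
#'
#' @param scene A [scene_spec].
#' @param classes List of [spectral_class_spec] objects.
#' @param side `"embryo"` or `"endosperm"` -- which face of the seeds looks
#'   at the camera.
#' @param labels Optional integer vector (length `seeds_per_plate`) of class
#'   indices into `classes`; defaults to cycling through all classes.
#' @param sp Side-dependent rendering parameters ([side_params()]).
#' @return A list with elements `raw` ([hypercube], state `"raw"`), `white`
#'   and `dark` (cols x bands reference matrices), `truth` (list with
#'   per-seed `class_id`, pixel `masks`, `centroids`, `areas` and noise-free
#'   `mean_spectra`), `side` and `scene`.
#' @export
generate_scene <- function(scene, classes, side = c("embryo", "endosperm"),
                           labels = NULL, sp = side_params()) {
  side <- match.arg(side)
  withr::with_seed(scene$rng_seed, {
    layout <- make_layout(scene, classes, labels)
    render_scene(layout, scene, classes, side = side, sp = sp)
  })
}

#' Generate the two faces of the same plate of seeds
#'
#' Draws one seed layout (identities, classes, per-seed offsets) and renders
#' it twice: once with the embryo side up and once with the endosperm side
#' up. Seed `k` in both bundles refers to the same kernel, so per-seed
#' spectra can later be paired and averaged across sides.
#'
#' @inheritParams generate_scene
#' @return List with elements `embryo` and `endosperm`, each as returned by
#'   [generate_scene()].
#' @export
paired_sides <- function(scene, classes, labels = NULL, sp = side_params()) {
  seeds <- derive_seeds(scene$rng_seed, 3L)
  layout <- withr::with_seed(seeds[1L], make_layout(scene, classes, labels))
  emb <- withr::with_seed(seeds[2L],
    render_scene(layout, scene, classes, side = "embryo", sp = sp))
  end <- withr::with_seed(seeds[3L],
    render_scene(layout, scene, classes, side = "endosperm", sp = sp))
  list(embryo = emb, endosperm = end)
}

#' Simulate a per-seed mean-spectra table directly (no imaging)
#'
#' Shortcut generator for the spectral stages: draws per-seed mean spectra
#' as class curve + flat per-seed offset + a smooth spectral noise curve
#' (per-band SD `noise_sd`, band correlation `noise_corr_bands`), skipping
#' image formation. With `planted_pair` set, the class curves are
#' made identical except at two bands, where class `k` receives an offset
#' `effect * (k - (K+1)/2)` at the numerator band and its negative at the
#' denominator band -- a construction whose band-ratio ANOVA argmax is the
#' planted pair by design.
#'
#' @param n_per_class Seeds per class.
#' @param classes List of [spectral_class_spec] objects.
#' @param wavelengths Band grid in nm (default: the 159-band working window
#'   of [default_wavelengths()]).
#' @param rng_seed Integer seed.
#' @param planted_pair Optional list with `num`, `den` (band indices) and
#'   optionally `effect` (reflectance offset step between adjacent classes;
#'   default `5 * noise_sd` of the first class).
#' @param side Side tag stored in the table.
#' @return A [spectra_table].
#' @export
simulate_spectra <- function(n_per_class, classes = default_class_specs(),
                             wavelengths = NULL, rng_seed = 1L,
                             planted_pair = NULL, side = "embryo") {
  if (is.null(wavelengths)) {
    wl <- default_wavelengths()
    wavelengths <- wl[wl >= 1000 & wl <= 2000]
  }
  check_wavelengths(wavelengths)
  K <- length(classes)
  nb <- length(wavelengths)
  curves <- lapply(classes, class_mean_spectrum, wavelengths = wavelengths)
  if (!is.null(planted_pair)) {
    effect <- planted_pair$effect %||% (5 * classes[[1L]]$noise_sd)
    base <- curves[[1L]]
    curves <- lapply(seq_len(K), function(k) {
      cv <- base
      cv[planted_pair$num] <- cv[planted_pair$num] + effect * (k - (K + 1) / 2)
      cv[planted_pair$den] <- cv[planted_pair$den] - effect * (k - (K + 1) / 2)
      cv
    })
  }
  n <- n_per_class * K
  withr::with_seed(rng_seed, {
    x <- matrix(NA_real_, n, nb)
    cls <- integer(n)
    row <- 1L
    for (k in seq_len(K)) {
      for (j in seq_len(n_per_class)) {
        off <- stats::rnorm(1, 0, classes[[k]]$seed_offset_sd)
        x[row, ] <- curves[[k]] + off +
          smooth_noise(nb, classes[[k]]$noise_sd,
                       classes[[k]]$noise_corr_bands)
        cls[row] <- classes[[k]]$class_id
        row <- row + 1L
      }
    }
    spectra_table(x, wavelengths, class = cls, side = side)
  })
}

#' Write ground truth as a JSON sidecar
#'
#' Masks are stored run-length encoded over column-major linear pixel
#' indices (`start`, `length` pairs, 1-based, half-open in the sense that a
#' run covers `start, ..., start + length - 1`).
#'
#' @param truth The `truth` element of a [generate_scene()] bundle.
#' @param path Output `.json` path.
#' @param image_dim Integer `c(rows, cols)` of the scene.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path, image_dim) {
  rle_masks <- lapply(truth$masks, function(px) {
    lin <- sort(px[, 1L] + (px[, 2L] - 1L) * image_dim[1L])
    breaks <- c(0L, which(diff(lin) != 1L), length(lin))
    starts <- lin[breaks[-length(breaks)] + 1L]
    lens <- diff(breaks)
    cbind(start = starts, length = lens)
  })
  obj <- list(image_dim = as.integer(image_dim),
              side = truth$side,
              seed_id = truth$seed_id,
              class_id = truth$class_id,
              areas = truth$areas,
              wavelengths = truth$wavelengths,
              mean_spectra = truth$mean_spectra,
              masks_rle = rle_masks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path Path written by [write_ground_truth()].
#' @return A truth list in the same shape as the `truth` element of
#'   [generate_scene()].
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$image_dim[1L]
  masks <- lapply(obj$masks_rle, function(m) {
    m <- matrix(as.integer(unlist(m)), ncol = 2L,
                dimnames = list(NULL, c("start", "length")))
    lin <- unlist(lapply(seq_len(nrow(m)), function(i)
      seq.int(m[i, 1L], length.out = m[i, 2L])))
    cbind(row = (lin - 1L) %% h + 1L, col = (lin - 1L) %/% h + 1L)
  })
  list(seed_id = obj$seed_id, class_id = obj$class_id, side = obj$side,
       masks = masks, areas = obj$areas,
       mean_spectra = obj$mean_spectra, wavelengths = obj$wavelengths)
}
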