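# Synthetic scene generator: sensor model, layout guarantees, determinism
# and convergence of extracted spectra to the specified class curves.

test_that("noise-free generation round-trips through calibration exactly", {
  sc <- test_scene(n_seeds = 1L, rng_seed = 3L, h = 40, w = 40)
  sc$background_noise_sd <- 0
  cls <- noise_free_classes(baselines = 0.5)
  bundle <- generate_scene(sc, cls, side = "endosperm",
                           sp = side_params(side_offset = 0))
  cal <- calibrate(bundle$raw, bundle$white, bundle$dark)
  px <- bundle$truth$masks[[1]]
  lin <- mask_linear(px, dim(cal)[1])
  m <- matrix(cal$values, prod(dim(cal)[1:2]), dim(cal)[3])
  expect_equal(max(abs(m[lin, ] - 0.5)), 0, tolerance = 1e-9)
  # background sits at its configured reflectance
  bg <- setdiff(seq_len(nrow(m)), lin)
  bg_refl <- (sc$background_level - sc$dark_level) /
    (sc$white_level - sc$dark_level)
  expect_equal(max(abs(m[bg, ] - bg_refl)), 0, tolerance = 1e-9)
})

test_that("a 3-class x 20-seed scene yields 60 disjoint in-bounds masks", {
  sc <- test_scene(n_seeds = 60L, rng_seed = 5L, h = 192, w = 256)
  bundle <- generate_scene(sc, default_class_specs())
  expect_length(bundle$truth$masks, 60L)
  expect_identical(as.vector(table(bundle$truth$class_id)), rep(20L, 3))
  lin <- lapply(bundle$truth$masks, mask_linear, h = sc$image_height)
  expect_identical(anyDuplicated(unlist(lin)), 0L)
  all_px <- do.call(rbind, bundle$truth$masks)
  expect_true(all(all_px[, 1] >= 1 & all_px[, 1] <= sc$image_height))
  expect_true(all(all_px[, 2] >= 1 & all_px[, 2] <= sc$image_width))
})

test_that("the same rng seed reproduces the scene bit for bit", {
  sc <- test_scene(n_seeds = 6L, rng_seed = 21L)
  a <- generate_scene(sc, default_class_specs())
  b <- generate_scene(sc, default_class_specs())
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$truth$mean_spectra, b$truth$mean_spectra)
  sc2 <- test_scene(n_seeds = 6L, rng_seed = 22L)
  c <- generate_scene(sc2, default_class_specs())
  expect_false(identical(a$raw$values, c$raw$values))
})

test_that("seeds that cannot fit their grid cell raise a placement error", {
  sc <- scene_spec(image_height = 40, image_width = 40, seeds_per_plate = 16,
                   seed_axes = list(major = c(8, 9), minor = c(6, 7)),
                   wavelength_grid = c(1000, 1100), rng_seed = 1)
  expect_error(generate_scene(sc, noise_free_classes(0.5)), "placement")
})

test_that("paired sides share seed identity and class; offsets off means equal spectra", {
  sc <- test_scene(n_seeds = 10L, rng_seed = 9L)
  pair <- paired_sides(sc, noise_free_classes(c(0.5, 0.4)),
                       sp = side_params(side_offset = 0, embryo_contrast = 0))
  expect_identical(pair$embryo$truth$seed_id, pair$endosperm$truth$seed_id)
  expect_identical(pair$embryo$truth$class_id, pair$endosperm$truth$class_id)
  expect_identical(pair$embryo$truth$masks, pair$endosperm$truth$masks)
  expect_equal(pair$embryo$truth$mean_spectra,
               pair$endosperm$truth$mean_spectra, tolerance = 1e-12)
})

test_that("side model shifts the endosperm face and darkens the embryo patch", {
  sc <- test_scene(n_seeds = 10L, rng_seed = 9L)
  sp <- side_params(side_offset = 0.02, embryo_contrast = -0.06)
  pair <- paired_sides(sc, noise_free_classes(0.5), sp = sp)
  d <- pair$endosperm$truth$mean_spectra - pair$embryo$truth$mean_spectra
  # endosperm = +offset, embryo mean = base + f * contrast with f in (0, 1)
  expect_true(all(d > 0.02))
  expect_true(all(d < 0.02 - sp$embryo_contrast))
})

test_that("class means of extracted seeds converge to the specified curves", {
  sc <- test_scene(n_seeds = 60L, rng_seed = 33L, h = 192, w = 256)
  cls <- default_class_specs()[2]
  bundle <- generate_scene(sc, cls, side = "endosperm",
                           sp = side_params(side_offset = 0))
  cube <- calibrate(bundle$raw, bundle$white, bundle$dark)
  regions <- split_seeds(build_mask(cube))
  tb <- extract_spectra(cube, regions, side = "endosperm")
  curve <- class_mean_spectrum(cls[[1]], cube$wavelengths)
  dev <- colMeans(tb$reflectance) - curve
  se <- apply(tb$reflectance, 2, sd) / sqrt(nrow(tb$reflectance))
  expect_lt(mean(abs(dev)), 3 * mean(se))
})

test_that("class curves stay inside [0,1] and refuse to leave it", {
  wl <- default_wavelengths()
  for (cl in default_class_specs()) {
    r <- class_mean_spectrum(cl, wl)
    expect_true(all(r >= 0 & r <= 1))
  }
  bad <- spectral_class_spec(2000L, 0.99,
                             extreme_separation = c(0.2, 0.2))
  expect_error(class_mean_spectrum(bad, wl), "\\[0, 1\\]")
})

test_that("smooth spectral noise has the requested marginal spread", {
  draws <- withr::with_seed(4, replicate(400, seedage:::smooth_noise(50, 0.02, 3)))
  expect_equal(sd(as.vector(draws)), 0.02, tolerance = 0.05)
  expect_identical(seedage:::smooth_noise(10, 0, 3), numeric(10))
})

test_that("ground truth survives a JSON sidecar round trip", {
  sc <- test_scene(n_seeds = 5L, rng_seed = 13L, h = 64, w = 64)
  bundle <- generate_scene(sc, default_class_specs())
  path <- file.path(withr::local_tempdir(), "truth.json")
  write_ground_truth(bundle$truth, path, dim(bundle$raw)[1:2])
  back <- read_ground_truth(path)
  expect_identical(back$class_id, bundle$truth$class_id)
  expect_equal(back$mean_spectra, unname(bundle$truth$mean_spectra),
               tolerance = 1e-12)
  for (k in seq_along(back$masks)) {
    expect_setequal(mask_linear(back$masks[[k]], sc$image_height),
                    mask_linear(bundle$truth$masks[[k]], sc$image_height))
  }
})
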