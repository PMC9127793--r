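# Radiometric calibration, spectral cropping and ENVI round trips.

make_test_cube <- function(h = 4, w = 5, nb = 6, seed = 1) {
  withr::with_seed(seed, {
    vals <- array(runif(h * w * nb, 100, 4000), c(h, w, nb))
    hypercube(vals, seq(1000, by = 50, length.out = nb), state = "raw")
  })
}

test_that("calibration maps white to 1, dark to 0 and affine mixtures to a", {
  h <- 4; w <- 5; nb <- 6
  withr::with_seed(2, {
    white <- array(runif(h * w * nb, 8000, 9000), c(h, w, nb))
    dark <- array(runif(h * w * nb, 80, 120), c(h, w, nb))
  })
  wl <- seq(1000, by = 50, length.out = nb)
  expect_equal(calibrate(hypercube(white, wl, "raw"), white, dark)$values,
               array(1, c(h, w, nb)))
  expect_equal(calibrate(hypercube(dark, wl, "raw"), white, dark)$values,
               array(0, c(h, w, nb)))
  for (a in c(0.1, 0.5, 0.9)) {
    mix <- dark + a * (white - dark)
    out <- calibrate(hypercube(mix, wl, "raw"), white, dark)
    expect_equal(out$values, array(a, c(h, w, nb)), tolerance = 1e-12)
    expect_identical(out$state, "corrected")
  }
})

test_that("per-column (cols x bands) references broadcast along the scan axis", {
  h <- 3; w <- 4; nb <- 2
  wl <- c(1000, 1100)
  white2d <- matrix(c(900, 950, 1000, 1050, 800, 850, 900, 950), w, nb)
  dark2d <- matrix(50, w, nb)
  refl <- array(runif(h * w * nb), c(h, w, nb))
  raw <- array(NA_real_, c(h, w, nb))
  for (b in seq_len(nb)) for (cc in seq_len(w)) {
    raw[, cc, b] <- dark2d[cc, b] + (white2d[cc, b] - dark2d[cc, b]) * refl[, cc, b]
  }
  out <- calibrate(hypercube(raw, wl, "raw"), white2d, dark2d)
  expect_equal(out$values, refl, tolerance = 1e-12)
  # a bare spatial frame (rows x cols) must be rejected: references are per band
  expect_error(calibrate(hypercube(raw, wl, "raw"), matrix(1, h, w),
                         matrix(0, h, w)),
               "cols x bands")
})

test_that("white == dark pixels are zeroed, counted, and warned about when common", {
  h <- 2; w <- 2; nb <- 2
  wl <- c(1000, 1100)
  white <- array(100, c(h, w, nb))
  dark <- array(50, c(h, w, nb))
  white[1, 1, 1] <- 50  # degenerate at one pixel-band
  raw <- hypercube(array(75, c(h, w, nb)), wl, "raw")
  expect_warning(out <- calibrate(raw, white, dark), "white == dark")
  expect_identical(attr(out, "n_degenerate"), 1L)
  expect_identical(out$values[1, 1, 1], 0)
  expect_true(all(is.finite(out$values)))
})

test_that("calibrating an already corrected cube or mismatched shapes errors", {
  cube <- make_test_cube()
  white <- array(1, dim(cube$values)); dark <- array(0, dim(cube$values))
  cal <- calibrate(cube, white, dark)
  expect_error(calibrate(cal, white, dark), "raw")
  expect_error(calibrate(cube, white[, , 1:3], dark), "dimensions")
})

test_that("cropping the default instrument grid to 1000-2000 nm keeps 159 bands", {
  wl <- default_wavelengths()
  cube <- hypercube(array(0.5, c(2, 2, length(wl))), wl, "corrected")
  cropped <- crop_bands(cube, 1000, 2000)
  expect_identical(length(cropped$wavelengths), 159L)
  expect_true(all(cropped$wavelengths >= 1000 & cropped$wavelengths <= 2000))
})

test_that("crop bounds are inclusive and empty windows error", {
  wl <- seq(1000, 2000, by = 100)
  cube <- hypercube(array(1, c(2, 2, 11)), wl, "corrected")
  expect_identical(length(crop_bands(cube, 1000, 2000)$wavelengths), 11L)
  expect_error(crop_bands(cube, 3000, 4000), "no bands")
})

test_that("nested crops compose: crop twice equals the inner crop", {
  cube <- make_test_cube(nb = 20)
  inner <- crop_bands(cube, 1200, 1600)
  twice <- crop_bands(crop_bands(cube, 1100, 1800), 1200, 1600)
  expect_equal(twice$values, inner$values)
  expect_equal(twice$wavelengths, inner$wavelengths)
})

test_that("ENVI float64 round trip is bit-identical for all interleaves", {
  cube <- make_test_cube(seed = 7)
  for (il in c("bsq", "bil", "bip")) {
    base <- file.path(withr::local_tempdir(), paste0("cube_", il))
    write_cube(cube, base, interleave = il, data_type = "float64")
    back <- read_cube(paste0(base, ".hdr"))
    expect_identical(back$values, cube$values)
    expect_identical(back$wavelengths, cube$wavelengths)
    expect_identical(back$state, "raw")
  }
})

test_that("float32 ENVI files preserve single-precision values exactly", {
  cube <- make_test_cube(seed = 8)
  dir <- withr::local_tempdir()
  write_cube(cube, file.path(dir, "a"), data_type = "float32")
  once <- read_cube(file.path(dir, "a.hdr"))
  write_cube(once, file.path(dir, "b"), data_type = "float32")
  twice <- read_cube(file.path(dir, "b.hdr"))
  expect_identical(twice$values, once$values)
  expect_equal(once$values, cube$values, tolerance = 1e-6)
})

test_that("BIL and BSQ files written from one array read back equal", {
  cube <- make_test_cube(seed = 9)
  dir <- withr::local_tempdir()
  write_cube(cube, file.path(dir, "x_bsq"), interleave = "bsq",
             data_type = "float64")
  write_cube(cube, file.path(dir, "x_bil"), interleave = "bil",
             data_type = "float64")
  expect_identical(read_cube(file.path(dir, "x_bsq"))$values,
                   read_cube(file.path(dir, "x_bil"))$values)
})

test_that("a header without a wavelength block is a parse error", {
  cube <- make_test_cube()
  dir <- withr::local_tempdir()
  write_cube(cube, file.path(dir, "c"))
  hdr <- readLines(file.path(dir, "c.hdr"))
  keep <- !grepl("wavelength", hdr) | grepl("units", hdr)
  drop_from <- grep("^wavelength = \\{", hdr)
  writeLines(hdr[seq_len(drop_from - 1L)], file.path(dir, "c.hdr"))
  expect_error(read_cube(file.path(dir, "c.hdr")), "wavelength")
})
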