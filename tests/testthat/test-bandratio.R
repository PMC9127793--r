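# One-way ANOVA F, the exhaustive two-band ratio search, and the
# two-threshold ratio classifier.

test_that("anova_f matches the closed-form hand computation", {
  expect_equal(anova_f(list(c(1, 2), c(1, 2), c(1, 2))), 0)
  expect_equal(anova_f(list(c(0, 1), c(10, 11))), 200)
  # location invariance
  g <- list(c(0.3, 0.7, 0.4), c(1.2, 1.4, 1.1), c(2.2, 2.0, 2.5))
  expect_equal(anova_f(g), anova_f(lapply(g, `+`, 17.3)), tolerance = 1e-12)
})

test_that("anova_f agrees with R's aov on 100 random group sets", {
  withr::with_seed(10, {
    for (rep in 1:100) {
      k <- sample(2:5, 1)
      groups <- lapply(seq_len(k), function(i)
        rnorm(sample(2:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2)))
      expect_equal(anova_f(groups), f_oracle(groups), tolerance = 1e-10)
    }
  })
})

test_that("degenerate within-group variance is handled explicitly", {
  expect_identical(anova_f(list(c(1, 1), c(2, 2))), Inf)
  expect_warning(f0 <- anova_f(list(c(3, 3), c(3, 3))), "identical")
  expect_identical(f0, 0)
  expect_error(anova_f(list(1, c(2, 3))), "at least 2 observations")
  expect_error(anova_f(list(c(1, 2))), "length")
})

test_that("a 2-band table yields exactly 2 valid F entries", {
  tb <- simulate_spectra(5, wavelengths = c(1000, 2000), rng_seed = 4)
  sr <- search_ratios(tb)
  expect_identical(sum(!is.na(sr$f_matrix)), 2L)
  expect_true(all(is.na(diag(sr$f_matrix))))
})

test_that("the vectorized search equals a per-pair brute-force oracle", {
  tb <- simulate_spectra(8, wavelengths = seq(1000, 2000, length.out = 12),
                         rng_seed = 6)
  x <- tb$reflectance
  sr <- search_ratios(tb)
  fo <- search_oracle(x, tb$class)
  expect_equal(sr$f_matrix, fo, tolerance = 1e-9)
  best <- which(fo == max(fo, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_identical(unname(sr$best_idx), unname(best))
})

test_that("F is invariant to class relabelling and global spectral scaling", {
  tb <- simulate_spectra(6, wavelengths = seq(1000, 2000, length.out = 8),
                         rng_seed = 12)
  sr <- search_ratios(tb)
  relab <- search_ratios(tb$reflectance,
                         labels = factor(as.integer(tb$class) %% 3),
                         wavelengths = tb$wavelengths)
  expect_equal(sr$f_matrix, relab$f_matrix, tolerance = 1e-9)
  scaled <- search_ratios(3.7 * tb$reflectance, labels = tb$class,
                          wavelengths = tb$wavelengths)
  expect_equal(sr$f_matrix, scaled$f_matrix, tolerance = 1e-9)
  # the matrix is genuinely asymmetric
  expect_false(isTRUE(all.equal(sr$f_matrix, t(sr$f_matrix))))
})

test_that("zero denominators invalidate a column but not the search", {
  withr::with_seed(3, x <- matrix(runif(30, 0.3, 0.9), 10, 3))
  x[4, 2] <- 0
  labels <- rep(c("a", "b"), each = 5)
  sr <- search_ratios(x, labels = labels, wavelengths = c(1000, 1500, 2000))
  expect_true(all(is.na(sr$f_matrix[, 2])))
  expect_false(sr$best_idx[["den"]] == 2L)
})

test_that("a planted discriminative pair is found by the search", {
  pp <- list(num = 30L, den = 120L)
  tb <- simulate_spectra(20, classes = iid_noise_classes(), rng_seed = 1,
                         planted_pair = pp)
  sr <- search_ratios(tb)
  # reciprocal orientation is equally discriminative by construction
  expect_setequal(unname(sr$best_idx), c(30L, 120L))
})

test_that("with shuffled labels the maximal F is at permutation-null level", {
  tb <- simulate_spectra(15, wavelengths = seq(1000, 2000, length.out = 15),
                         rng_seed = 20)
  withr::with_seed(21, {
    shuffled <- sample(tb$class)
    obs <- max(search_ratios(tb$reflectance, labels = shuffled,
                             wavelengths = tb$wavelengths)$f_matrix,
               na.rm = TRUE)
    null_max <- replicate(200, {
      max(search_ratios(tb$reflectance, labels = sample(tb$class),
                        wavelengths = tb$wavelengths)$f_matrix, na.rm = TRUE)
    })
  })
  expect_lt(obs, quantile(null_max, 0.995))
  expect_gt(obs, quantile(null_max, 0.005))
})

test_that("perfectly separated classes give accuracy 1 with cuts in the gaps", {
  r <- c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3, 2.1, 2.2, 2.3)
  lab <- rep(c("c2018", "c2019", "c2020"), each = 3)
  m <- fit_thresholds(r, lab)
  expect_equal(m$accuracy, 1)
  expect_true(m$t1 > 0.3 && m$t1 < 1.1)
  expect_true(m$t2 > 1.3 && m$t2 < 2.1)
  expect_identical(m$class_order, c("c2018", "c2019", "c2020"))
  pred <- predict_thresholds(m, r)
  expect_identical(as.character(pred), lab)
})

test_that("fitted thresholds attain the exhaustive-oracle optimum", {
  withr::with_seed(30, {
    for (rep in 1:50) {
      n <- sample(9:50, 1)
      lab <- sample(rep(c("a", "b", "c"), length.out = n))
      centers <- sort(runif(3, 0, 3))
      r <- centers[match(lab, c("a", "b", "c"))] + rnorm(n, 0, runif(1, 0.1, 1))
      m <- fit_thresholds(r, lab)
      expect_equal(m$accuracy, threshold_oracle_accuracy(r, lab),
                   tolerance = 1e-12)
      # round trip: predicting the fit data reproduces the fit criterion
      acc <- mean(as.character(predict_thresholds(m, r)) == lab)
      expect_equal(acc, m$accuracy, tolerance = 1e-12)
    }
  })
})

test_that("the binary variant fits a single cut", {
  r <- c(0.1, 0.2, 0.9, 1.0)
  lab <- c("aged", "aged", "new", "new")
  m <- fit_thresholds(r, lab)
  expect_true(is.na(m$t2))
  expect_equal(m$accuracy, 1)
  expect_identical(as.character(predict_thresholds(m, c(0.15, 0.95))),
                   c("aged", "new"))
})

test_that("prediction follows the boundary-belongs-left convention", {
  m <- fit_thresholds(c(1, 1.1, 2, 2.1, 3, 3.1),
                      rep(c("a", "b", "c"), each = 2))
  expect_identical(as.character(predict_thresholds(m, m$t1)), "a")
  expect_identical(as.character(predict_thresholds(m, m$t2)), "b")
  expect_identical(as.character(predict_thresholds(m, -10)), "a")
  expect_identical(as.character(predict_thresholds(m, 10)), "c")
  expect_warning(pred <- predict_thresholds(m, c(1, NaN)), "non-finite")
  expect_true(is.na(pred[2]))
})

test_that("degenerate ratio sets are contract errors", {
  expect_error(fit_thresholds(rep(1, 6), rep(c("a", "b", "c"), 2)),
               "distinct")
  expect_error(fit_thresholds(1:4, c("a", "b", "c", "d")), "2 or 3 classes")
})
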