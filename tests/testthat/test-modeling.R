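# Calibration/prediction splitting, SVM grid search, evaluation and the
# end-to-end pipeline contracts.

coarse_svm <- svm_spec(cost_grid = 2^seq(-10, 10, 4),
                       gamma_grid = 2^seq(-10, 10, 4), folds = 3)

blobs <- function(n_per_class, centers, sd = 0.1, seed = 1, d = 2) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(centers, function(cc)
      matrix(rnorm(n_per_class * d, cc, sd), n_per_class, d)))
  })
  list(x = x, y = factor(rep(seq_along(centers), each = n_per_class)))
}

test_that("the stratified split reproduces the study's 240/120 design", {
  labels <- rep(c(2018, 2019, 2020), each = 120)
  tags <- split_calibration(labels, 240, rng_seed = 3)
  expect_identical(sum(tags == "prediction"), 120L)
  tab <- table(labels[tags == "calibration"])
  expect_identical(as.vector(tab), rep(80L, 3))
  expect_identical(tags, split_calibration(labels, 240, rng_seed = 3))
  expect_false(identical(tags, split_calibration(labels, 240, rng_seed = 4)))
  expect_error(split_calibration(labels, 360), "smaller")
  expect_error(split_calibration(c("a", "a", "b"), 2), "at least 2 seeds")
})

test_that("well-separated classes are classified perfectly", {
  d <- blobs(20, centers = c(-2, 0, 2), sd = 0.1)
  split <- split_calibration(d$y, 42, rng_seed = 1)
  cal <- split == "calibration"
  m <- train_svm(d$x[cal, ], d$y[cal], spec = coarse_svm)
  ev <- evaluate(m, d$x, d$y, split)
  expect_equal(ev$prediction$accuracy, 100)
  expect_equal(ev$calibration$accuracy, 100)
  expect_true(all(diag(ev$prediction$confusion) ==
                    rowSums(ev$prediction$confusion)))
})

test_that("ties in the CV grid go to the smallest cost then gamma", {
  d <- blobs(10, centers = c(-2, 2), sd = 0.05)
  m <- train_svm(d$x, d$y, spec = coarse_svm)
  g <- m$grid
  top <- g[g$cv_accuracy == max(g$cv_accuracy), ]
  expect_equal(m$cost, min(top$cost))
  expect_equal(m$gamma, min(top$gamma[top$cost == min(top$cost)]))
})

test_that("permuted labels score at chance level on a balanced 3-class task", {
  withr::with_seed(60, {
    x <- matrix(rnorm(360 * 5), 360, 5)
    y <- factor(sample(rep(c("a", "b", "c"), 120)))
  })
  split <- split_calibration(y, 240, rng_seed = 2)
  cal <- split == "calibration"
  m <- train_svm(x[cal, ], y[cal], spec = coarse_svm)
  acc <- evaluate(m, x, y, split)$prediction$accuracy
  # binomial 95% band around 1/3 at n = 120
  expect_gt(acc, 24.9)
  expect_lt(acc, 41.8)
})

test_that("duplicating every calibration row barely moves the chosen grid point", {
  d <- blobs(15, centers = c(-2, 0, 2), sd = 0.2, seed = 5)
  m1 <- train_svm(d$x, d$y, spec = coarse_svm)
  m2 <- train_svm(rbind(d$x, d$x), factor(c(d$y, d$y)), spec = coarse_svm)
  expect_lte(abs(log2(m1$cost) - log2(m2$cost)), 4)
  expect_lte(abs(log2(m1$gamma) - log2(m2$gamma)), 4)
})

test_that("degenerate inputs are contract errors", {
  expect_error(train_svm(matrix(rnorm(10), 5, 2), rep("a", 5), coarse_svm),
               "2 classes")
  expect_error(train_svm(matrix(c(1, Inf, 3, 4), 2, 2), c("a", "b"),
                         coarse_svm), "finite")
})

test_that("reports count accuracy and reject unseen labels", {
  truth <- rep(c("a", "b", "c"), each = 4)
  perfect <- report_classification(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$confusion == diag(4, 3)))
  onec <- report_classification(rep("a", 12), truth)
  expect_equal(onec$accuracy, 100 / 3, tolerance = 1e-10)
  expect_error(report_classification(rep("z", 12), truth), "unseen")
})

test_that("the binary collapse maps the newest year to 'new'", {
  y <- c(2018, 2019, 2020, 2020)
  expect_identical(as.character(collapse_binary(y)),
                   c("aged", "aged", "new", "new"))
  cm3 <- table(truth = factor(c(2018, 2019, 2020)),
               pred = factor(c(2018, 2019, 2020)))
  bin <- table(truth = collapse_binary(rownames(cm3)[row(cm3)][cm3 > 0]),
               pred = collapse_binary(colnames(cm3)[col(cm3)][cm3 > 0]))
  expect_true(all(bin == diag(c(2, 1))))
  expect_error(collapse_binary(c("x", "y")), "new_class")
})

test_that("the pipeline writes 18 reports plus the binary task, deterministically", {
  cfg <- pipeline_config(n_per_class = 8, seeds_per_plate = 8,
                         image_height = 96, image_width = 128,
                         seed_axes = list(major = c(6, 8), minor = c(4, 6)),
                         svm = coarse_svm, cal_frac = 0.625,
                         data_seed = 5, split_seed = 2)
  out <- run_pipeline(cfg)
  expect_length(out$reports, 18L)
  sides <- vapply(out$reports, `[[`, character(1), "side")
  expect_identical(as.vector(table(sides)), c(4L, 7L, 7L))  # both/embryo/endosperm
  expect_identical(out$binary$representation, "fusion_binary")
  expect_true(all(vapply(out$reports, function(r)
    r$prediction_accuracy >= 0 && r$prediction_accuracy <= 100, logical(1))))
  # threshold report's calibration accuracy equals the fit criterion
  expect_equal(out$reports$embryo_ratio_threshold$calibration_accuracy,
               out$artifacts$embryo$threshold_cal_accuracy, tolerance = 1e-9)
  out2 <- run_pipeline(cfg)
  expect_identical(
    vapply(out$reports, `[[`, numeric(1), "prediction_accuracy"),
    vapply(out2$reports, `[[`, numeric(1), "prediction_accuracy"))
  expect_identical(out$artifacts$embryo$best_pair,
                   out2$artifacts$embryo$best_pair)
  expect_error(run_pipeline(list()), "invalid pipeline config")
})

test_that("config YAML round trip overrides known keys and rejects unknown ones", {
  dir <- withr::local_tempdir()
  writeLines(c("n_per_class: 6", "seeds_per_plate: 6", "data_seed: 9"),
             file.path(dir, "cfg.yaml"))
  cfg <- read_pipeline_config(file.path(dir, "cfg.yaml"))
  expect_identical(cfg$n_per_class, 6L)
  expect_identical(cfg$data_seed, 9L)
  writeLines("nonsense: 1", file.path(dir, "bad.yaml"))
  expect_error(read_pipeline_config(file.path(dir, "bad.yaml")), "unknown")
})
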