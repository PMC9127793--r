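# Independent brute-force oracles used to verify the package's vectorized
# implementations. These deliberately use naive loops and a different code
# path from the package.

# First-order histogram statistics by explicit per-level loop.
hs_oracle <- function(levels, L, as_printed = FALSE) {
  n <- length(levels)
  p <- numeric(L)
  for (z in 0:(L - 1L)) p[z + 1L] <- sum(levels == z) / n
  mu <- 0
  for (z in 0:(L - 1L)) mu <- mu + z * p[z + 1L]
  consistency <- 0
  for (z in 0:(L - 1L)) consistency <- consistency + p[z + 1L]^2
  contrast <- 0
  for (z in 0:(L - 1L)) contrast <- contrast + (z - mu)^2 * p[z + 1L]
  m3 <- m4 <- 0
  for (z in 0:(L - 1L)) {
    m3 <- m3 + (z - mu)^3 * p[z + 1L]
    m4 <- m4 + (z - mu)^4 * p[z + 1L]
  }
  if (contrast == 0) {
    skew <- kurt <- 0
  } else if (as_printed) {
    skew <- m3 / contrast^3
    kurt <- m4 / contrast^4
  } else {
    skew <- m3 / sqrt(contrast)^3
    kurt <- m4 / sqrt(contrast)^4
  }
  entropy <- 0
  for (z in 0:(L - 1L)) {
    if (p[z + 1L] > 0) entropy <- entropy - p[z + 1L] * log2(p[z + 1L])
  }
  c(H_intensity = mu, H_consistency = consistency, H_skewness = skew,
    H_kurtosis = kurt, H_contrast = contrast, H_entropy = entropy)
}

# Co-occurrence matrix by explicit pixel loop (0 degrees, distance 1).
glcm_oracle <- function(img, L) {
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img) - 1L)) {
      a <- img[r, cc]; b <- img[r, cc + 1L]
      if (!is.na(a) && !is.na(b)) counts[a + 1L, b + 1L] <-
          counts[a + 1L, b + 1L] + 1
    }
  }
  counts / sum(counts)
}

# GLCM features by explicit double loops over matrix entries.
glcm_features_oracle <- function(P) {
  L <- nrow(P)
  mu_i <- mu_j <- 0
  for (i in 0:(L - 1L)) for (j in 0:(L - 1L)) {
    mu_i <- mu_i + i * P[i + 1L, j + 1L]
    mu_j <- mu_j + j * P[i + 1L, j + 1L]
  }
  v_i <- v_j <- 0
  for (i in 0:(L - 1L)) for (j in 0:(L - 1L)) {
    v_i <- v_i + (i - mu_i)^2 * P[i + 1L, j + 1L]
    v_j <- v_j + (j - mu_j)^2 * P[i + 1L, j + 1L]
  }
  sd_i <- sqrt(v_i); sd_j <- sqrt(v_j)
  contrast <- energy <- homog <- corr <- 0
  for (i in 0:(L - 1L)) for (j in 0:(L - 1L)) {
    p <- P[i + 1L, j + 1L]
    contrast <- contrast + abs(i - j)^2 * p
    energy <- energy + p^2
    homog <- homog + p / (1 + abs(i - j))
    if (sd_i * sd_j > 0) corr <- corr + (i - mu_i) * (j - mu_j) * p / (sd_i * sd_j)
  }
  c(G_contrast = contrast, G_correlation = corr, G_energy = energy,
    G_homogeneity = homog)
}

# Generic one-way ANOVA F via R's model fitting machinery.
f_oracle <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  summary(stats::aov(y ~ g))[[1]][["F value"]][1L]
}

# Exhaustive O(n^2) search over midpoint cut pairs for the 3-class
# threshold rule; returns the best achievable calibration accuracy.
threshold_oracle_accuracy <- function(ratios, labels) {
  labels <- factor(labels)
  ord <- levels(labels)[order(tapply(ratios, labels, mean))]
  sr <- sort(unique(ratios))
  cuts <- (sr[-length(sr)] + sr[-1L]) / 2
  best <- 0
  for (t1 in cuts) for (t2 in cuts) {
    if (t2 <= t1) next
    pred <- ifelse(ratios <= t1, ord[1L],
                   ifelse(ratios <= t2, ord[2L], ord[3L]))
    best <- max(best, mean(pred == as.character(labels)))
  }
  best
}

# Exhaustive F over all ordered band pairs by direct per-pair computation.
search_oracle <- function(x, labels) {
  p <- ncol(x)
  f <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || any(x[, j] == 0)) next
    f[i, j] <- anova_f(split(x[, i] / x[, j], labels))
  }
  f
}

# Simple argrelextrema-style scan: strict interior local maxima/minima.
scan_extrema_oracle <- function(y) {
  n <- length(y)
  idx <- integer()
  for (i in 2:(n - 1L)) {
    if ((y[i] > y[i - 1L] && y[i] > y[i + 1L]) ||
        (y[i] < y[i - 1L] && y[i] < y[i + 1L])) idx <- c(idx, i)
  }
  idx
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

mask_linear <- function(px, h) px[, 1L] + (px[, 2L] - 1L) * h

# Small scene presets used across tests (reduced spatial scale, working
# band window only, so suites stay fast).
test_scene <- function(n_seeds = 12L, rng_seed = 11L, h = 96L, w = 128L) {
  wl <- default_wavelengths()
  scene_spec(image_height = h, image_width = w, seeds_per_plate = n_seeds,
             seed_axes = list(major = c(6, 8), minor = c(4, 6)),
             wavelength_grid = wl[wl >= 1000 & wl <= 2000],
             rng_seed = rng_seed)
}

# Rank-3 data with exactly known components: orthonormal mean-zero scores
# times fixed variances times planted orthonormal loading curves. The
# sample covariance is exactly V diag(s^2) V' / (n-1), so prcomp recovers
# the planted loadings up to sign, and the PC3 loading is the planted
# curve with extrema at known band indices.
planted_rank3 <- function(n = 100, p = 159,
                          extrema = c(20L, 60L, 110L, 140L), seed = 5) {
  t <- seq_len(p)
  b3 <- exp(-((t - extrema[1]) / 9)^2) - exp(-((t - extrema[2]) / 11)^2) +
    exp(-((t - extrema[3]) / 10)^2) - exp(-((t - extrema[4]) / 8)^2)
  b1 <- 1 + 0.002 * t + 1e-5 * t^2
  b2 <- sin(2 * pi * t / p)
  v3 <- b3 / sqrt(sum(b3^2))
  v1 <- b1 - sum(b1 * v3) * v3
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- b2 - sum(b2 * v3) * v3 - sum(b2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  V <- cbind(v1, v2, v3)
  withr::with_seed(seed, {
    Z <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(Z))
  })
  X <- Q %*% diag(c(20, 6, 1)) %*% t(V) + matrix(0.4, n, p)
  list(x = X, V = V, extrema = extrema)
}

noise_free_classes <- function(baselines = c(0.5, 0.4, 0.3)) {
  lapply(seq_along(baselines), function(i)
    spectral_class_spec(2017L + i, baselines[i], feature_bands = list(),
                        noise_sd = 0, seed_offset_sd = 0))
}

# Classes with independent per-band noise: the construction under which a
# planted discriminative band pair is guaranteed to be the F argmax (with
# band-correlated noise, near-adjacent ratios can score higher because
# their noise cancels).
iid_noise_classes <- function() {
  lapply(default_class_specs(), function(cl) {
    cl$noise_corr_bands <- 0
    cl
  })
}
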