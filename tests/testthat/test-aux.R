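test_that("rolling correlation honours exact limits and the global window", {
  x <- ar1_sim(120, 0.6, seed = 1)
  same <- rolling_correlation(x, x, windows = c(20, 30), n_surr = 20, seed = 1)
  expect_true(all(abs(same$r - 1) < 1e-12))
  opp <- rolling_correlation(x, -x, windows = 20, n_surr = 20, seed = 1)
  expect_true(all(abs(opp$r + 1) < 1e-12))

  y <- ar1_sim(120, 0.6, seed = 2)
  full <- rolling_correlation(x, y, windows = length(x), n_surr = 20, seed = 2)
  expect_equal(full$r, cor(x, y), tolerance = 1e-12)
  expect_error(rolling_correlation(x, y, windows = 500), "window")
})

test_that("independent AR(1) pairs rarely show significant rolling windows", {
  frac <- mean(vapply(1:4, function(seed) {
    a <- ar1_sim(300, 0.8, seed = seed * 3)
    b <- ar1_sim(300, 0.8, seed = seed * 3 + 1)
    rc <- rolling_correlation(a, b, windows = c(20, 50), n_surr = 100,
                              seed = seed)
    mean(rc$significant, na.rm = TRUE)
  }, numeric(1)))
  expect_lte(frac, 0.1)
})

test_that("unit-variance PCA satisfies its algebraic identities", {
  sim <- simulate_element_counts(200, seed = 3)
  p <- pca_unit_variance(sim$counts)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # loadings sign convention: dominant loading positive
  L <- as.matrix(p$loadings[, -1])
  expect_true(all(apply(L, 2, function(l) l[which.max(abs(l))]) > 0))
  # full reconstruction of the standardized matrix
  m <- scale(as.matrix(sim$counts[, -1]))
  recon <- as.matrix(p$scores) %*% t(L)
  expect_lt(max(abs(recon - m)), 1e-10)

  # two correlated columns: PC1 fraction is (1+|r|)/2 exactly
  set.seed(4)
  a <- rnorm(500); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(500)
  p2 <- pca_unit_variance(tibble::tibble(u = a, v = b))
  r <- cor(a, b)
  expect_equal(p2$variance_fraction[1], (1 + abs(r)) / 2, tolerance = 1e-12)

  bad <- tibble::tibble(depth = 1:10, Ca = rnorm(10), Fe = rep(1, 10))
  expect_error(pca_unit_variance(bad), "Fe")
})

test_that("two-factor element tables yield the construction variance fractions", {
  sim <- simulate_element_counts(600, seed = 5)
  lc <- sim$counts
  lc[, -1] <- log(lc[, -1] + 0.5)
  p <- pca_unit_variance(lc)
  expect_lt(max(abs(p$variance_fraction[1:2] -
                      sim$truth$expected_var_frac[1:2])), 0.03)
})

test_that("red-noise spectrum detects an orbital-band line on a jittered grid", {
  set.seed(6)
  tt <- sort(runif(400, 0, 480))
  x <- 1.5 * sin(2 * pi * tt / 100) + 0.7 * ar1_sim(400, 0.8, seed = 7)
  sp <- rednoise_spectrum(tibble::tibble(age = tt, value = x),
                          n_mc = 300, seed = 8)
  tb <- sp$table
  band <- tb$freq > 1 / 120 & tb$freq < 1 / 85
  expect_true(any(tb$power[band] > tb$p95[band]))
  expect_true(all(tb$p80 <= tb$p90 & tb$p90 <= tb$p95))
  expect_true(all(tb$power >= 0))
  expect_error(rednoise_spectrum(paleo_ts(1:40, rep(1, 40))), "constant")
})

test_that("evolutive spectra track stationary and drifting wavelengths", {
  depth <- seq(0, 60, 0.02)
  sine <- tibble::tibble(depth = depth, value = sin(2 * pi * depth / 14))
  es <- evolutive_spectrum(sine, resample_step = 0.02, window = 28, step = 4)
  ridge <- dplyr::summarise(dplyr::group_by(es, center),
                            peak = freq[which.max(power)], .groups = "drop")
  expect_true(all(abs(ridge$peak - 1 / 14) < 0.015))

  # chirp from 16 m down to 12 m wavelength: ridge frequency drifts upward
  lam <- seq(16, 12, length.out = length(depth))
  phase <- cumsum(2 * pi * 0.02 / lam)
  chirp <- tibble::tibble(depth = depth, value = sin(phase))
  ec <- evolutive_spectrum(chirp, resample_step = 0.02, window = 24, step = 6)
  ridge2 <- dplyr::summarise(dplyr::group_by(ec, center),
                             peak = freq[which.max(power)], .groups = "drop")
  fit <- coef(lm(peak ~ center, data = ridge2))[2]
  expect_gt(fit, 0)

  zero <- tibble::tibble(depth = depth, value = 0)
  ez <- evolutive_spectrum(zero, resample_step = 0.02, window = 24, step = 6)
  expect_true(all(ez$power == 0))
  expect_error(evolutive_spectrum(sine, window = 1000), "longer")
})
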