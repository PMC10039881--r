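test_that("coupled_logistic reduces to the uncoupled map and is deterministic", {
  s <- coupled_logistic(50, b_xy = 0, b_yx = 0, x0 = 0.4, y0 = 0.3, seed = 1)
  manual <- Reduce(function(x, .) x * (3.8 - 3.8 * x), 1:149, 0.4,
                   accumulate = TRUE)
  expect_equal(s$x$value, manual[101:150], tolerance = 1e-12)

  a <- coupled_logistic(200, seed = 7)
  b <- coupled_logistic(200, seed = 7)
  expect_identical(a$x$value, b$x$value)
  expect_identical(a$y$value, b$y$value)

  expect_error(coupled_logistic(200, b_xy = 3, seed = 1), "coupling")
  expect_error(coupled_logistic(100, r_x = 3.2), "rates")
})

test_that("one-way coupling into the driven map is detectable by cross-mapping", {
  # x (r = 3.8) drives y (r = 3.5): true direction x -> y, low linear
  # correlation, strong cross-map asymmetry
  detected <- vapply(1:3, function(seed) {
    s <- coupled_logistic(800, b_xy = 0, b_yx = 0.32, seed = seed)
    x <- s$x$value; y <- s$y$value
    true_dir <- cross_map_estimate(x, y, E = 2, tau = 1)$skill
    absent <- cross_map_estimate(y, x, E = 2, tau = 1)$skill
    abs(cor(x, y)) < 0.5 && true_dir > 0.9 && true_dir > absent + 0.3
  }, logical(1))
  expect_true(all(detected))
})

test_that("the driven variable's manifold recovers the forcing variable best", {
  # with b_xy > 0 the y map forces x, so estimating y from x's manifold
  # outperforms the reverse (moderate coupling: strong coupling to the
  # period-4 orbit of the r = 3.5 map synchronizes the whole system)
  s <- coupled_logistic(800, b_xy = 0.1, b_yx = 0, seed = 3)
  y_from_x <- cross_map_estimate(s$y$value, s$x$value, E = 2, tau = 1)$skill
  x_from_y <- cross_map_estimate(s$x$value, s$y$value, E = 2, tau = 1)$skill
  expect_gt(y_from_x, x_from_y)
})

test_that("paleo system honours degenerate forcing and threshold limits", {
  # forcing permanently above the switch-on threshold: constant forest
  s <- simulate_paleo_system(n_kyr = 100, sigma = 0, obs_sd = 0,
                             precip_up = -50, precip_down = -60,
                             jitter = 0, seed = 1)
  expect_true(all(s$vegetation$value == s$truth$level_high))

  # zero hysteresis width, zero noise: vegetation is a step function of
  # precipitation
  s2 <- simulate_paleo_system(n_kyr = 200, sigma = 0, obs_sd = 0,
                              precip_up = 0, precip_down = 0,
                              jitter = 0, seed = 2)
  joint <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(s2$precipitation), p = value),
    dplyr::rename(tibble::as_tibble(s2$vegetation), v = value), by = "age")
  hi <- joint$v == s2$truth$level_high
  expect_true(all(joint$p[hi] >= 0) || mean(xor(hi, joint$p > 0)) < 0.02)

  expect_error(simulate_paleo_system(precip_up = -1, precip_down = 1),
               "precip_down")
})

test_that("sine-forced occupancy of the high regime matches the arcsin formula", {
  # pure sine forcing standardized to unit variance has amplitude sqrt(2);
  # a threshold at half the amplitude gives occupancy 1/2 - arcsin(1/2)/pi
  thr <- sqrt(2) / 2
  s <- simulate_paleo_system(n_kyr = 500, periods = 100, amplitudes = 1,
                             sigma = 0, obs_sd = 0, response_lag = 0,
                             precip_up = thr, precip_down = thr,
                             jitter = 0, seed = 5)
  frac_high <- mean(s$vegetation$value == s$truth$level_high)
  expect_equal(frac_high, 0.5 - asin(0.5) / pi, tolerance = 0.02)
})

test_that("hysteresis produces a bimodal vegetation response in the overlap band", {
  s <- simulate_paleo_system(n_kyr = 500, seed = 3)
  joint <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(to_uniform_grid(s$precipitation, 1)), x = value),
    dplyr::rename(tibble::as_tibble(to_uniform_grid(s$vegetation, 1)), y = value),
    by = "age")
  joint <- dplyr::filter(joint, is.finite(x), is.finite(y))
  bh <- binned_histograms(joint, x, y,
                          x_bin_edges = quantile(joint$x, seq(0, 1, 0.125),
                                                 names = FALSE))
  expect_true(any(bh$bimodality$bimodal, na.rm = TRUE))
  expect_equal(sum(bh$histograms$count), nrow(joint))
})

test_that("element-count generator is seed-deterministic with recoverable factors", {
  a <- simulate_element_counts(100, seed = 11)
  b <- simulate_element_counts(100, seed = 11)
  expect_identical(a$counts, b$counts)

  # single factor, no noise: log-count matrix is rank one up to rounding
  L <- default_element_loadings(); L[, 2] <- 0
  r1 <- simulate_element_counts(150, loadings = L, factor_sd = c(1, 0),
                                noise_sd = 0, seed = 2)
  lc <- log(as.matrix(r1$counts[, -1]) + 0.5)
  sv <- svd(scale(lc, scale = FALSE))$d
  expect_lt(sv[2] / sv[1], 0.02)
})
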