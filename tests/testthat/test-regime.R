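step_data <- function(n, x0 = 0.5, sd = 5, seed = 1,
                      low = 20, high = 80) {
  set.seed(seed)
  x <- runif(n)
  tibble::tibble(x = x, y = pmin(100, pmax(0, ifelse(x < x0, low, high) +
                                             rnorm(n, 0, sd))))
}

test_that("threshold fit recovers a constructed step with its plateaus", {
  d <- step_data(400, seed = 3)
  m <- fit_threshold_response(d)
  expect_lt(abs(m$x_star - 0.5), 0.05)
  expect_equal(m$plateau_low, 20, tolerance = 3)
  expect_equal(m$plateau_high, 80, tolerance = 3)
  expect_false(m$threshold_unreliable)
  # mid-level-crossing alternative lands in the same place
  expect_lt(abs(m$x_star_midlevel - 0.5), 0.05)
})

test_that("threshold location is translation-equivariant in the proxy", {
  d <- step_data(400, seed = 4)
  m0 <- fit_threshold_response(d)
  m1 <- fit_threshold_response(dplyr::mutate(d, x = x + 2))
  expect_equal(m1$x_star - m0$x_star, 2, tolerance = 0.02)
})

test_that("a purely linear response is flagged unreliable", {
  set.seed(5)
  d <- tibble::tibble(x = runif(300), y = 30 + 40 * x + rnorm(300, 0, 1))
  m <- fit_threshold_response(d)
  expect_true(m$threshold_unreliable)
  expect_error(fit_threshold_response(d[1:40, ]), "at least")
})

test_that("binned histograms conserve mass and see a single mode when there is one", {
  set.seed(6)
  d <- tibble::tibble(x = runif(200), y = rep(80, 200))
  bh <- binned_histograms(d, x, y, x_bin_edges = c(0, 0.5, 1))
  expect_equal(sum(bh$histograms$count), 200)
  expect_true(all(!bh$bimodality$bimodal, na.rm = TRUE))
  expect_true(all(bh$bimodality$high_mass[bh$bimodality$n > 0] == 1))
  expect_error(binned_histograms(d, x, y, x_bin_edges = c(1, 0)), "increasing")
})

test_that("regime classification partitions the percentage scale", {
  expect_equal(classify_regime(c(20, 50, 80)),
               c("steppe", "intermediate", "forest"))
  expect_equal(classify_regime(c(35, 65)), c("intermediate", "intermediate"))
  expect_error(classify_regime(120), "0, 100")
  y <- seq(0, 100, 0.5)
  expect_false(anyNA(classify_regime(y)))
})

test_that("conditioning masks follow the predicate and report occupancy", {
  pair <- tibble::tibble(age = 1:100, value = runif(100, 0, 100))
  co2 <- paleo_ts(1:100, rep(280, 100))
  m <- conditional_subset(pair, co2)
  expect_true(all(m$data$mask))
  expect_equal(m$summary$mask_fraction, 1)

  co2_low <- paleo_ts(1:100, rep(250, 100))
  expect_warning(m2 <- conditional_subset(pair, co2_low), "never holds")
  expect_equal(m2$summary$mask_fraction, 0)

  set.seed(7)
  cond <- paleo_ts(1:400, rnorm(400))
  med <- median(cond$value)
  pair2 <- tibble::tibble(age = 1:400, value = runif(400, 0, 100))
  m3 <- conditional_subset(pair2, cond, predicate = function(v) v >= med)
  expect_equal(m3$summary$mask_fraction, 0.5, tolerance = 0.05)

  expect_error(conditional_subset(tibble::tibble(age = 500:600, value = 1),
                                  paleo_ts(1:100, 1:100)), "overlap")
})
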