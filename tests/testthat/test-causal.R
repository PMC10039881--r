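test_that("circular-shift surrogates are value-preserving rotations", {
  x <- rnorm(100)
  s <- make_surrogates(x, 10, "circular-shift", seed = 1)
  for (i in 1:10) expect_equal(sort(s$surrogates[, i]), sort(x))
  expect_identical(s$surrogates,
                   make_surrogates(x, 10, "circular-shift", seed = 1)$surrogates)
  expect_error(make_surrogates(x, 1), "at least 2")
})

test_that("fourier-phase surrogates preserve the amplitude spectrum and moments", {
  for (n in c(128, 129)) {            # even and odd lengths
    x <- ar1_sim(n, 0.7, seed = n)
    s <- make_surrogates(x, 5, "fourier-phase", seed = 2)
    for (i in 1:5) {
      y <- s$surrogates[, i]
      expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-8)
      expect_equal(mean(y), mean(x), tolerance = 1e-10)
      expect_equal(var(y), var(x), tolerance = 1e-8)
    }
  }
})

test_that("fourier-phase surrogates keep the AR(1) autocorrelation structure", {
  x <- ar1_sim(500, 0.8, seed = 5)
  s <- make_surrogates(x, 50, "fourier-phase", seed = 3)
  ac1 <- apply(s$surrogates, 2, function(y) cor(y[-1], y[-length(y)]))
  expect_equal(mean(ac1), 0.8, tolerance = 0.1)
})

test_that("envelope test passes above the surrogate band and fails inside it", {
  s <- coupled_logistic(400, b_xy = 0, b_yx = 0.3, seed = 2)
  cc <- ccm_convergence(s$x$value, s$y$value, E = 2, tau = 1,
                        lib_sizes = c(50, 200), n_samples = 10, seed = 1)
  nL <- nrow(cc$summary)
  below <- matrix(runif(nL * 100, -0.1, 0.1), nL)
  expect_true(envelope_test(cc, below)$pass)
  at_level <- matrix(rep(cc$summary$mean_skill + 0.2, 100), nL)
  expect_false(envelope_test(cc, at_level)$pass)
  expect_error(envelope_test(cc, below[1, , drop = FALSE][rep(1, 5), ]),
               "one row per library size")
  b <- envelope_test(cc, below)$bands
  expect_true(all(b$lower <= b$upper))
})

test_that("rank-based AUC matches exhaustive pair enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.85, 0.1)), 0.75)
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(77)
  for (i in 1:20) {
    real <- round(runif(sample(1:50, 1)), 2)
    surr <- round(runif(sample(1:50, 1)), 2)
    expect_equal(roc_auc(real, surr), oracle_auc(real, surr))
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("causality classes require both envelope escape and AUC separation", {
  expect_equal(classify_causality(TRUE, 0.95)$class, "significant")
  expect_equal(classify_causality(TRUE, 0.85)$class, "weak")
  expect_equal(classify_causality(TRUE, 0.75)$class, "none")
  expect_equal(classify_causality(FALSE, 0.95)$class, "none")
  # a positive-displacement ruling disqualifies whatever the AUC says
  v <- classify_causality(TRUE, 0.95, direction = "ruled-out")
  expect_equal(v$class, "none")
  expect_equal(v$auc_class, "significant")
})

test_that("delayed profile covers the displacement grid and finds synchrony at zero", {
  x <- ar1_sim(400, 0.8, seed = 9)
  p <- delayed_ccm_profile(x, x, E = 2, tau = 1, n_boot = 30, seed = 4)
  expect_equal(nrow(p$profile), 21)
  expect_lte(abs(p$optimal_tp), 1)
  expect_true(all(abs(p$profile$tp[p$considered]) < 9))
  expect_error(delayed_ccm_profile(x[1:50], x[1:50], E = 2, tau = 1,
                                   lib_size = 100), "too short")
})

test_that("direction rulings follow the displacement sign conventions", {
  fake <- function(opt) structure(list(optimal_tp = opt), class = "delayed_ccm")
  expect_equal(direction_verdict(fake(4), fake(-1))$ruling, "ruled-out")
  expect_equal(direction_verdict(fake(0), fake(0))$ruling, "synchrony-suspected")
  d <- direction_verdict(fake(-1), fake(-5))
  expect_equal(d$ruling, "causal")
  expect_equal(d$asymmetry, 4)
})

test_that("verdicts are stable under age-model shifts for strong synthetic coupling", {
  sys <- simulate_paleo_system(n_kyr = 420, seed = 8)
  cfg <- ccm_config(n_surr = 30, n_samples = 15, min_overlap = 150, seed = 2)
  sens <- sensitivity_age_shift(sys$precipitation, sys$vegetation,
                                config = cfg, deltas = c(-5, 0, 5),
                                delayed = FALSE)
  expect_equal(nrow(sens$verdicts), 3)
  expect_true(is.logical(sens$stable))
  single <- sensitivity_age_shift(sys$precipitation, sys$vegetation,
                                  config = cfg, deltas = 0, delayed = FALSE)
  expect_true(single$stable)
})
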