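test_that("delay embedding follows the Takens construction", {
  d <- delay_embed(c(1, 2, 3, 4, 5), E = 2, tau = 1)
  expect_equal(d$emb, matrix(c(2, 3, 4, 5, 1, 2, 3, 4), ncol = 2))
  expect_equal(d$t, 2:5)

  x <- rnorm(50)
  expect_equal(delay_embed(x, E = 1)$emb[, 1], x)
  expect_equal(nrow(delay_embed(x, E = 3, tau = 2)$emb), 50 - 4)
  expect_error(delay_embed(x[1:4], E = 3, tau = 2), "too short")
})

test_that("simplex projection forecasts deterministic dynamics and not noise", {
  th <- 2 * pi * (1:200) / 20
  expect_gt(simplex_forecast(sin(th), E = 2, tau = 1, tp = 1)$skill, 0.999)

  s <- coupled_logistic(500, b_xy = 0, b_yx = 0, seed = 4)
  expect_gt(simplex_forecast(s$x$value, E = 2, tau = 1, tp = 1)$skill, 0.95)

  low <- vapply(1:10, function(seed) {
    set.seed(seed + 400)
    abs(simplex_forecast(rnorm(500), E = 2, tau = 1, tp = 1)$skill) < 0.15
  }, logical(1))
  expect_gte(sum(low), 9)
})

test_that("embedding scan is exhaustive, sorted, deterministic, and oracle-consistent", {
  s <- coupled_logistic(400, b_xy = 0, b_yx = 0, seed = 6)
  sc <- select_embedding(s$x$value)
  expect_equal(nrow(sc), 40)
  expect_true(all(diff(sc$skill) <= 1e-12))
  expect_identical(sc, select_embedding(s$x$value))

  # oracle scan over a reduced grid agrees on the winner
  grid <- expand.grid(E = 1:4, tau = 1:2)
  osk <- mapply(function(E, tau) oracle_simplex(s$x$value, E, tau, 1)$skill,
                grid$E, grid$tau)
  obest <- grid[which.max(osk), ]
  sc2 <- select_embedding(s$x$value, E_range = 1:4, tau_range = 1:2)
  expect_equal(sc2$E[1], obest$E)
  expect_equal(sc2$tau[1], obest$tau)
})

test_that("cross-mapping attains perfect self-skill and stays null for noise", {
  # a periodic orbit revisits states exactly, so the zero-distance
  # convention reproduces the series perfectly
  per <- rep(sin(2 * pi * (1:20) / 20), 5)
  expect_equal(cross_map_estimate(per, per, E = 2, tau = 1)$skill, 1,
               tolerance = 1e-12)
  # on an aperiodic attractor leave-one-out keeps self-skill marginally
  # below exact unity
  s <- coupled_logistic(300, b_xy = 0, b_yx = 0, seed = 8)
  x <- s$x$value
  expect_gt(cross_map_estimate(x, x, E = 2, tau = 1)$skill, 0.999)

  low <- vapply(1:10, function(seed) {
    set.seed(seed + 900)
    abs(cross_map_estimate(rnorm(500), rnorm(500), E = 2, tau = 1)$skill) < 0.2
  }, logical(1))
  expect_gte(sum(low), 9)
})

test_that("convergence curve is seed-reproducible and consistent with the full map", {
  s <- coupled_logistic(400, b_xy = 0, b_yx = 0.3, seed = 10)
  x <- s$x$value; y <- s$y$value
  n_emb <- length(y) - 1
  cc <- ccm_convergence(x, y, E = 2, tau = 1, lib_sizes = n_emb,
                        n_samples = 1, seed = 3)
  full <- cross_map_estimate(x, y, E = 2, tau = 1)$skill
  expect_equal(cc$summary$mean_skill, full, tolerance = 1e-12)

  a <- ccm_convergence(x, y, E = 2, tau = 1, n_samples = 10, seed = 42)
  b <- ccm_convergence(x, y, E = 2, tau = 1, n_samples = 10, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_error(ccm_convergence(x, y, E = 2, tau = 1, lib_sizes = c(2, 50)),
               "at least")
})

test_that("cross-map skill grows with library length in the forced direction", {
  wins <- vapply(1:6, function(seed) {
    s <- coupled_logistic(600, b_xy = 0, b_yx = 0.32, seed = seed + 20)
    cc <- ccm_convergence(s$x$value, s$y$value, E = 2, tau = 1,
                          lib_sizes = c(50, 400), n_samples = 30,
                          seed = seed)
    sm <- cc$summary
    sm$mean_skill[sm$lib_size == 400] > sm$mean_skill[sm$lib_size == 50]
  }, logical(1))
  expect_gte(sum(wins), 5)
})
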