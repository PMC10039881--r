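#' Coupled logistic maps with known causal direction
#'
#' The standard two-species testbed for cross-mapping:
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t - b_{xy} y_t)}
#' \deqn{y_{t+1} = y_t (r_y - r_y y_t - b_{yx} x_t)}
#' `b_xy` is the strength with which y forces x (so `b_xy > 0, b_yx = 0`
#' means the causal arrow is y -> x). The first `burn` steps are discarded
#' as transient.
#'
#' @param n Output length after burn-in.
#' @param r_x,r_y Growth rates, in (3.5, 4].
#' @param b_xy,b_yx Coupling strengths (>= 0).
#' @param x0,y0 Initial states in (0,1); drawn from the seed when `NULL`.
#' @param seed Integer seed; identical seeds give identical output.
#' @param burn Transient steps discarded (default 100).
#' @return List with `paleo_ts` components `x`, `y` (unit "state", 1-step
#'   grid) and a `truth` list recording couplings and the seed.
#' @export
#' @examples
#' sim <- coupled_logistic(500, b_xy = 0.32, b_yx = 0, seed = 1)
#' head(sim$x)
coupled_logistic <- function(n, r_x = 3.8, r_y = 3.5, b_xy = 0.32, b_yx = 0,
                             x0 = NULL, y0 = NULL, seed = 1, burn = 100) {
  if (r_x < 3.5 || r_x > 4 || r_y < 3.5 || r_y > 4) {
    abort("growth rates must lie in [3.5, 4].")
  }
  if (b_xy < 0 || b_yx < 0) abort("couplings must be nonnegative.")
  with_seed(seed, {
    if (is.null(x0)) x0 <- runif(1, 0.2, 0.8)
    if (is.null(y0)) y0 <- runif(1, 0.2, 0.8)
  })
  if (x0 <= 0 || x0 >= 1 || y0 <= 0 || y0 >= 1) abort("x0, y0 must lie in (0,1).")
  total <- n + burn
  x <- numeric(total); y <- numeric(total)
  x[1] <- x0; y[1] <- y0
  for (t in seq_len(total - 1)) {
    x[t + 1] <- x[t] * (r_x - r_x * x[t] - b_xy * y[t])
    y[t + 1] <- y[t] * (r_y - r_y * y[t] - b_yx * x[t])
    if (!is.finite(x[t + 1]) || !is.finite(y[t + 1]) ||
        x[t + 1] <= 0 || x[t + 1] >= 1 || y[t + 1] <= 0 || y[t + 1] >= 1) {
      abort("trajectory left (0,1); reduce the coupling strength.")
    }
  }
  idx <- (burn + 1):total
  list(
    x = paleo_ts(seq_len(n), x[idx], label = "x", unit = "state"),
    y = paleo_ts(seq_len(n), y[idx], label = "y", unit = "state"),
    truth = list(b_xy = b_xy, b_yx = b_yx, r_x = r_x, r_y = r_y,
                 x0 = x0, y0 = y0, seed = seed)
  )
}

# AR(1) innovations with stationary unit variance, burned in for ~10
# correlation times.
ar1_series <- function(n, phi, sd = 1) {
  burn <- if (phi > 0 && phi < 1) min(5000L, ceiling(10 / (1 - phi))) else 50L
  e <- rnorm(n + burn)
  x <- as.numeric(stats::filter(e * sqrt(1 - phi^2), phi, method = "recursive"))
  sd * x[(burn + 1):(n + burn)]
}

#' Orbital forcing -> lagged precipitation -> hysteretic vegetation chain
#'
#' Emulates the causal chain the pipeline is designed to recover: a
#' quasi-orbital forcing (sum of sinusoids at 100/41/23 kyr plus AR(1)
#' noise), a precipitation proxy responding to the forcing with a fixed
#' lag, and a vegetation cover that switches between two stable regime
#' levels with hysteresis — jumping to the high (forest) level when
#' precipitation exceeds `precip_up` and collapsing to the low (steppe)
#' level when it falls below `precip_down`. Series are built on a fine
#' uniform grid, then subsampled onto an irregular (jittered) age grid so
#' the interpolation stage is genuinely exercised.
#'
#' @param n_kyr Time span in kyr (default 500).
#' @param periods,amplitudes Sinusoid periods (kyr) and amplitudes.
#' @param phi,sigma AR(1) coefficient (per base step) and noise scale used
#'   for both forcing and precipitation noise.
#' @param response_lag Precipitation lag behind forcing, kyr (default 5).
#' @param precip_up,precip_down Switching thresholds on the precipitation
#'   scale; `precip_down <= precip_up` (hysteresis width = difference).
#' @param level_low,level_high Vegetation regime levels in percent.
#' @param obs_sd Observation noise on vegetation, percent.
#' @param base_step Fine grid step in kyr (default 0.2, emulating the
#'   ~209-yr resolution of a dense pollen record).
#' @param jitter Uniform age jitter applied to the irregular sampling grid,
#'   as a fraction of `base_step`.
#' @param seed Integer seed.
#' @return List of `paleo_ts` `forcing`, `precipitation`, `vegetation`
#'   (irregular grids, ages in kyr BP) and a `truth` list with lag,
#'   thresholds, levels, noise scales and the seed.
#' @export
simulate_paleo_system <- function(n_kyr = 500,
                                  periods = c(100, 41, 23),
                                  amplitudes = c(1, 0.55, 0.35),
                                  phi = 0.95, sigma = 0.3,
                                  response_lag = 5,
                                  precip_up = 0.3, precip_down = -0.3,
                                  level_low = 20, level_high = 80,
                                  obs_sd = 5,
                                  base_step = 0.2, jitter = 0.3,
                                  seed = 1) {
  if (precip_down > precip_up) abort("`precip_down` must be <= `precip_up`.")
  with_seed(derive_seed(seed, "paleo_system"), {
    lag_steps <- round(response_lag / base_step)
    n <- round(n_kyr / base_step) + 1L
    total <- n + lag_steps
    tt <- seq(0, by = base_step, length.out = total)   # kyr, internal clock
    forcing <- rowSums(vapply(seq_along(periods), function(i) {
      ph <- runif(1, 0, 2 * pi)
      amplitudes[i] * sin(2 * pi * tt / periods[i] + ph)
    }, numeric(total))) + ar1_series(total, phi, sigma)
    forcing <- as.numeric(scale(forcing))
    precip <- forcing[seq_len(n)] +
      ar1_series(n, phi, sigma)       # response to forcing lag_steps earlier
    forcing_now <- forcing[(lag_steps + 1):total]      # forcing at obs time
    # hysteretic two-state switch driven by precipitation
    state <- numeric(n)
    state[1] <- if (precip[1] >= (precip_up + precip_down) / 2) 1 else 0
    for (t in 2:n) {
      state[t] <- if (precip[t] > precip_up) 1
                  else if (precip[t] < precip_down) 0
                  else state[t - 1]
    }
    veg <- ifelse(state == 1, level_high, level_low) + rnorm(n, 0, obs_sd)
    veg <- pmin(100, pmax(0, veg))
    # ages in kyr BP: observation clock runs toward the present
    age <- rev(seq(0, by = base_step, length.out = n))
    irregular <- function(a, v) {
      off <- runif(length(a), -jitter * base_step / 2, jitter * base_step / 2)
      aj <- sort(a + off)
      keep <- c(TRUE, diff(aj) > 1e-9)
      paleo_ts(aj[keep], v[order(a + off)][keep])
    }
    f_ts <- irregular(age, rev(forcing_now)); attr(f_ts, "label") <- "forcing"
    p_ts <- irregular(age, rev(precip)); attr(p_ts, "label") <- "precipitation"
    v_ts <- irregular(age, rev(veg)); attr(v_ts, "label") <- "vegetation"
    attr(v_ts, "unit") <- "%"
    list(forcing = f_ts, precipitation = p_ts, vegetation = v_ts,
         truth = list(response_lag = response_lag,
                      precip_up = precip_up, precip_down = precip_down,
                      level_low = level_low, level_high = level_high,
                      phi = phi, sigma = sigma, obs_sd = obs_sd,
                      base_step = base_step, jitter = jitter, seed = seed))
  })
}

#' Factor-structured synthetic XRF element counts
#'
#' Builds a depth-by-element count table whose log-counts follow a
#' two-factor model `log mu = mean + loadings %*% factors + noise`, the
#' structure unit-variance PCA is expected to recover. Default loadings
#' mimic a siliciclastic-vs-carbonate axis (positive Al, Fe, K, Mn, Si,
#' Ti; negative Ca, S) and a sulfur/redox axis.
#'
#' @param n Number of samples.
#' @param loadings 9 x 2 matrix (rows named by element).
#' @param factor_sd Standard deviations of the two factor series (their
#'   squared ratio is the factor-variance ratio).
#' @param phi AR(1) coefficient of the factor series.
#' @param noise_sd Log-scale observation noise.
#' @param mean_log Baseline log-count (default `log(5000)`).
#' @param seed Integer seed.
#' @return List with `counts` (tibble: `depth` + element columns) and
#'   `truth` (loadings, factor series, expected unit-variance PCA
#'   variance fractions from the construction covariance).
#' @export
simulate_element_counts <- function(n = 300,
                                    loadings = default_element_loadings(),
                                    factor_sd = c(sqrt(3), 1),
                                    phi = 0.7,
                                    noise_sd = 0.1,
                                    mean_log = log(5000),
                                    seed = 1) {
  stopifnot(ncol(loadings) == 2)
  with_seed(derive_seed(seed, "element_counts"), {
    f <- cbind(ar1_series(n, phi, 1), ar1_series(n, phi, 1))
    # rescale realized factors to the exact specified variances so the
    # recorded ground truth is exact rather than subject to sampling noise
    f <- sweep(scale(f), 2, factor_sd, "*")
    eps <- matrix(rnorm(n * nrow(loadings), 0, noise_sd), n)
    logmu <- mean_log + f %*% t(loadings) + eps
    counts <- matrix(pmax(0, round(exp(logmu))), n,
                     dimnames = list(NULL, rownames(loadings)))
  })
  # expected unit-variance PCA fractions from the construction covariance
  cov_log <- loadings %*% diag(factor_sd^2) %*% t(loadings) +
    diag(noise_sd^2, nrow(loadings))
  corr <- stats::cov2cor(cov_log)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  list(
    counts = dplyr::bind_cols(tibble::tibble(depth = seq_len(n) * 0.04),
                              tibble::as_tibble(counts)),
    truth = list(loadings = loadings, factor_sd = factor_sd, phi = phi,
                 noise_sd = noise_sd, seed = seed,
                 expected_var_frac = ev / sum(ev))
  )
}

#' Default two-factor element loadings
#'
#' @return A 9 x 2 loadings matrix over Al, Ca, Fe, K, Mn, P, S, Si, Ti.
#' @export
default_element_loadings <- function() {
  el <- c("Al", "Ca", "Fe", "K", "Mn", "P", "S", "Si", "Ti")
  l1 <- c(0.8, -0.9, 0.7, 0.8, 0.5, 0.1, -0.6, 0.8, 0.8)
  l2 <- c(0.1, -0.4, 0.5, 0.0, -0.5, 0.1, 0.8, 0.0, 0.3)
  matrix(c(l1, l2), ncol = 2, dimnames = list(el, c("F1", "F2")))
}
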