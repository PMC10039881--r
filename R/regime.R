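#' Smooth threshold-response fit (regime-shift model)
#'
#' Fits forest cover (%) against a precipitation proxy with a penalized
#' cubic-regression-spline GAM (basis dimension `k`, smoothness by
#' generalized cross-validation) and extracts the regime structure: the
#' threshold `x_star` where the fitted curve rises fastest (argmax of the
#' finite-difference derivative on a dense grid), the low/high plateau
#' levels (mean fit over the outer deciles of x), a mid-level-crossing
#' alternative threshold, and the x-bands below/above which one regime
#' accounts for at least 90% of observations.
#'
#' @param data Data frame of paired observations.
#' @param x,y Bare column names of the proxy and response (defaults `x`,
#'   `y`).
#' @param k Spline basis dimension (default 25).
#' @param grid_n Grid resolution for the derivative (default 1000).
#' @return A `regime_model` with `tidy()`, `glance()` and `autoplot()`
#'   methods. `threshold_unreliable` is set when the derivative peaks at
#'   the edge of the data support (e.g. for a purely linear response).
#' @export
#' @examples
#' d <- tibble::tibble(x = seq(0, 1, length.out = 200),
#'                     y = ifelse(x < 0.5, 20, 80) + rnorm(200, 0, 2))
#' glance(fit_threshold_response(d))
fit_threshold_response <- function(data, x = x, y = y, k = 25, grid_n = 1000) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3 * k) {
    abort(sprintf("need at least %d paired observations for k = %d.", 3 * k, k))
  }
  df <- data.frame(x = xv, y = yv)
  fit <- mgcv::gam(y ~ s(x, bs = "cr", k = k), data = df, method = "GCV.Cp")
  grid <- seq(min(xv), max(xv), length.out = grid_n)
  fhat <- as.numeric(predict(fit, newdata = data.frame(x = grid)))
  deriv <- c(NA, diff(fhat) / diff(grid))
  imax <- which.max(abs(deriv))
  x_star <- grid[imax]
  edge <- imax <= ceiling(grid_n * 0.02) | imax >= floor(grid_n * 0.98)
  # near-flat derivative profile (linear response) is also unreliable
  dr <- abs(deriv[-1])
  flat <- (max(dr) - min(dr)) < 0.1 * max(abs(dr))
  lo_dec <- xv <= quantile(xv, 0.1); hi_dec <- xv >= quantile(xv, 0.9)
  plateau_low <- mean(fhat[grid <= quantile(xv, 0.1)])
  plateau_high <- mean(fhat[grid >= quantile(xv, 0.9)])
  mid <- (plateau_low + plateau_high) / 2
  cross <- which(diff(sign(fhat - mid)) != 0)
  x_star_mid <- if (length(cross)) grid[cross[1]] else NA_real_
  # regime-prevalence bands: x below/above which >=90% of points are in
  # one regime (steppe <35%, forest >65%)
  band <- function(side) {
    cand <- sort(unique(xv))
    keep <- vapply(cand, function(c0) {
      sel <- if (side == "low") xv <= c0 else xv >= c0
      n <- sum(sel)
      if (n < 10) return(NA)
      if (side == "low") mean(yv[sel] < 35) >= 0.9 else mean(yv[sel] > 65) >= 0.9
    }, logical(1))
    if (!any(keep, na.rm = TRUE)) return(NA_real_)
    if (side == "low") max(cand[which(keep)]) else min(cand[which(keep)])
  }
  structure(list(fit = fit, k = k, n = length(xv),
                 grid = tibble::tibble(x = grid, fitted = fhat, derivative = deriv),
                 x_star = x_star, x_star_midlevel = x_star_mid,
                 plateau_low = plateau_low, plateau_high = plateau_high,
                 steppe_band_upper = band("low"), forest_band_lower = band("high"),
                 threshold_unreliable = edge || flat,
                 data = tibble::tibble(x = xv, y = yv)),
            class = "regime_model")
}

#' @export
print.regime_model <- function(x, ...) {
  cat(sprintf(
    "Threshold-response fit (cr spline, k=%d, n=%d)\n  threshold x* = %.3f%s (mid-level crossing %.3f)\n  plateaus: low %.1f, high %.1f\n",
    x$k, x$n, x$x_star, if (x$threshold_unreliable) " [unreliable]" else "",
    x$x_star_midlevel, x$plateau_low, x$plateau_high))
  invisible(x)
}

#' @export
tidy.regime_model <- function(x, ...) x$grid

#' @export
glance.regime_model <- function(x, ...) {
  tibble::tibble(x_star = x$x_star, x_star_midlevel = x$x_star_midlevel,
                 plateau_low = x$plateau_low, plateau_high = x$plateau_high,
                 steppe_band_upper = x$steppe_band_upper,
                 forest_band_lower = x$forest_band_lower,
                 threshold_unreliable = x$threshold_unreliable,
                 n = x$n, k = x$k)
}

#' Per-proxy-bin histograms of the response with a bimodality flag
#'
#' Bins the proxy axis, histograms the response within each bin, and
#' flags bins where both regime modes (response below 35 and above 65)
#' each hold at least 10% of the bin's mass — the bimodality signature
#' of two coexisting stable states.
#'
#' @param data Data frame of paired observations.
#' @param x,y Bare column names (defaults `x`, `y`).
#' @param x_bin_edges Increasing numeric vector of proxy bin edges.
#' @param y_bin_width Response bin width (default 5).
#' @return List with `histograms` (tibble: x_bin, y_mid, count) and
#'   `bimodality` (tibble: x_bin, n, low_mass, high_mass, bimodal;
#'   `bimodal` is `NA` for empty bins).
#' @export
binned_histograms <- function(data, x = x, y = y, x_bin_edges,
                              y_bin_width = 5) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  if (is.unsorted(x_bin_edges, strictly = TRUE)) abort("bin edges must be increasing.")
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  xb <- cut(xv, x_bin_edges, include.lowest = TRUE)
  y_edges <- seq(0, 100 + y_bin_width, by = y_bin_width)
  yb <- cut(pmin(yv, 100), y_edges, include.lowest = TRUE)
  hist <- dplyr::count(
    tibble::tibble(x_bin = xb, y_bin = yb,
                   y_mid = y_edges[as.integer(yb)] + y_bin_width / 2),
    .data$x_bin, .data$y_bin, .data$y_mid, .drop = FALSE, name = "count")
  hist <- dplyr::filter(hist, !is.na(.data$x_bin))
  hist$y_mid[is.na(hist$y_mid)] <- y_edges[as.integer(hist$y_bin[is.na(hist$y_mid)])] + y_bin_width / 2
  bim <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(x_bin = xb, y = yv), .data$x_bin, .drop = FALSE),
    n = dplyr::n(),
    low_mass = mean(.data$y < 35),
    high_mass = mean(.data$y > 65),
    .groups = "drop")
  bim <- dplyr::filter(bim, !is.na(.data$x_bin))
  bim$bimodal <- ifelse(bim$n == 0, NA,
                        bim$low_mass >= 0.1 & bim$high_mass >= 0.1)
  list(histograms = hist, bimodality = bim)
}

#' Classify tree-pollen percentages into vegetation regimes
#'
#' Steppe below 35% tree pollen, forest above 65%, intermediate between.
#'
#' @param y Numeric vector of tree-pollen percentages in \[0, 100\].
#' @return Character vector of `"steppe"`, `"intermediate"`, `"forest"`.
#' @export
#' @examples
#' classify_regime(c(20, 50, 80))
classify_regime <- function(y) {
  if (any(y < 0 | y > 100, na.rm = TRUE)) abort("percentages must lie in [0, 100].")
  out <- rep(NA_character_, length(y))
  out[y < 35] <- "steppe"
  out[y > 65] <- "forest"
  out[y >= 35 & y <= 65] <- "intermediate"
  out
}

#' Mask a proxy pair on an interpolated conditioning series
#'
#' Interpolates a conditioning series (e.g. ice-core CO2) onto the
#' pair's age grid and masks observations where `predicate` holds —
#' e.g. restricting the forest/precipitation cross-plot to intervals of
#' CO2 above 260 ppmv (full interglacial conditions).
#'
#' @param pair Data frame with an `age` column (plus any value columns).
#' @param conditioning Series data frame (`age`, `value`).
#' @param predicate Function of the interpolated conditioning values
#'   returning a logical mask (default `>= 260`).
#' @return List with `data` (pair + `cond_value`, `mask` columns) and
#'   `summary` (mask fraction, per-regime occupancy if a
#'   `tree_pollen_pct` or `y` column is present).
#' @export
conditional_subset <- function(pair, conditioning,
                               predicate = function(v) v >= 260) {
  if (!"age" %in% names(pair)) abort("`pair` needs an `age` column.")
  check_series(conditioning, "conditioning")
  lo <- max(min(pair$age), min(conditioning$age))
  hi <- min(max(pair$age), max(conditioning$age))
  if (lo >= hi) abort("no overlap between the pair's and the conditioning series' age ranges.")
  cv <- approx(conditioning$age, conditioning$value, xout = pair$age,
               rule = 1)$y
  mask <- predicate(cv) & !is.na(cv)
  if (!any(mask, na.rm = TRUE)) warn("conditioning predicate never holds; empty mask.")
  out <- dplyr::mutate(tibble::as_tibble(pair), cond_value = cv, mask = mask)
  ycol <- intersect(c("tree_pollen_pct", "y", "value"), names(pair))[1]
  occ <- if (!is.na(ycol)) {
    y <- pair[[ycol]]
    tibble::tibble(
      regime = c("steppe", "intermediate", "forest"),
      inside = vapply(c("steppe", "intermediate", "forest"),
                      function(r) mean(classify_regime(y[mask]) == r, na.rm = TRUE),
                      numeric(1)),
      outside = vapply(c("steppe", "intermediate", "forest"),
                       function(r) mean(classify_regime(y[!mask]) == r, na.rm = TRUE),
                       numeric(1)))
  } else NULL
  list(data = out,
       summary = list(mask_fraction = mean(mask, na.rm = TRUE), occupancy = occ))
}
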