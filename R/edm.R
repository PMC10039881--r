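#' Takens delay embedding
#'
#' Reconstructs the state space of a uniformly sampled series as delay
#' vectors \eqn{(x_t, x_{t-\tau}, \ldots, x_{t-(E-1)\tau})}. Series are
#' taken in chronological order (index increasing toward the present);
#' the pipeline reverses kyr BP series before embedding.
#'
#' @param x Numeric vector (uniform grid, chronological order) or a data
#'   frame with a `value` column.
#' @param E Embedding dimension (1–10 in scans).
#' @param tau Time delay in grid steps.
#' @return Tibble with column `t` (index of the vector's most recent
#'   coordinate) and an `emb` matrix-column of the lagged coordinates.
#' @export
delay_embed <- function(x, E, tau = 1) {
  x <- series_values(x)
  n <- length(x)
  need <- (E - 1) * tau + 2
  if (n < need) {
    abort(sprintf("series too short: need at least %d points for E=%d, tau=%d.",
                  need, E, tau))
  }
  t_idx <- seq((E - 1) * tau + 1, n)
  emb <- vapply(0:(E - 1), function(j) x[t_idx - j * tau], numeric(length(t_idx)))
  emb <- matrix(emb, nrow = length(t_idx))
  tibble::tibble(t = t_idx, emb = emb)
}

series_values <- function(x) {
  if (is.data.frame(x)) x <- x$value
  x <- as.numeric(x)
  if (anyNA(x)) abort("series contains missing values; extract a contiguous block first.")
  x
}

# Embed `embed_on` once and attach the tp-displaced target values of
# `target_series` to each embedded row; reused across library draws.
embed_target <- function(embed_on, target_series, E, tau, tp) {
  d <- delay_embed(embed_on, E, tau)
  n <- length(embed_on)
  target <- rep(NA_real_, nrow(d$emb))
  tt <- d$t + tp
  ok <- tt >= 1 & tt <= n
  target[ok] <- target_series[tt[ok]]
  list(emb = d$emb, t = d$t, target = target,
       pred = seq_len(nrow(d$emb))[ok], k = E + 1L)
}

# Skill of one library draw against a prepared embedding/target; the hot
# path of every resampling loop.
et_skill <- function(et, lib = et$pred) {
  est <- edm_predict_cpp(et$emb, et$target, as.integer(lib),
                         as.integer(et$pred), et$k)
  skill_cor(et$target[et$pred], est)
}

# Shared prediction core: embed `embed_on`, predict `target_series` tp steps
# ahead of each vector's time, with neighbours restricted to `lib` rows.
edm_predict <- function(embed_on, target_series, E, tau, tp, lib = NULL) {
  et <- embed_target(embed_on, target_series, E, tau, tp)
  if (is.null(lib)) lib <- et$pred
  if (length(lib) - 1L < E + 1L) {
    abort(sprintf("library too small: need at least %d usable neighbours.", E + 1L))
  }
  est <- edm_predict_cpp(et$emb, et$target, as.integer(lib),
                         as.integer(et$pred), et$k)
  tibble::tibble(t = et$t[et$pred], observed = et$target[et$pred],
                 predicted = est)
}

skill_cor <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(obs[ok]) == 0 || sd(pred[ok]) == 0) return(NA_real_)
  cor(obs[ok], pred[ok])
}

#' Simplex-projection forecast skill
#'
#' Leave-one-out nearest-neighbour forecasting on the delay-embedded
#' attractor: each point's value `tp` steps ahead is predicted from its
#' E+1 nearest neighbours, weighted `exp(-d_i/d_min)`, using the entire
#' series as both library and prediction set. Skill is the Pearson
#' correlation between predictions and observations.
#'
#' @inheritParams delay_embed
#' @param tp Forecast horizon in steps (>= 1 for forecasting).
#' @return List with `predictions` (tibble `t`, `observed`, `predicted`)
#'   and `skill` (rho; `NA` with a warning when degenerate).
#' @export
#' @examples
#' x <- coupled_logistic(300, b_xy = 0, b_yx = 0, seed = 2)$x
#' simplex_forecast(x, E = 2, tau = 1)$skill
simplex_forecast <- function(x, E, tau = 1, tp = 1) {
  v <- series_values(x)
  pr <- edm_predict(v, v, E, tau, tp)
  rho <- skill_cor(pr$observed, pr$predicted)
  if (is.na(rho)) warn("forecast skill undefined (zero variance).")
  list(predictions = pr, skill = rho)
}

#' Exhaustive embedding-parameter scan
#'
#' Ranks all (E, tau) combinations by univariate simplex forecast skill,
#' the criterion used to pick cross-mapping parameters. Ties are broken
#' toward smaller E, then smaller tau; the scan is fully deterministic.
#'
#' @inheritParams simplex_forecast
#' @param E_range,tau_range Integer vectors scanned exhaustively
#'   (defaults 1–10 and 1–4).
#' @return Tibble with `E`, `tau`, `skill`, sorted nonincreasing in skill.
#' @export
select_embedding <- function(x, E_range = 1:10, tau_range = 1:4, tp = 1) {
  v <- series_values(x)
  grid <- tidyr::expand_grid(E = E_range, tau = tau_range)
  grid$skill <- purrr::map2_dbl(grid$E, grid$tau, function(E, tau) {
    tryCatch(suppressWarnings(simplex_forecast(v, E, tau, tp)$skill),
             error = function(e) NA_real_)
  })
  dplyr::arrange(grid, dplyr::desc(.data$skill), .data$E, .data$tau)
}

#' Cross-map estimate of a candidate cause from an effect's manifold
#'
#' If A forces B, B's reconstructed attractor encodes A's states, so A can
#' be estimated from B's delay embedding. Neighbours are found in the
#' effect's shadow manifold (optionally restricted to a library subset)
#' and the cause's contemporaneous — or `tp`-displaced — values are
#' averaged with simplex weights. Negative `tp` estimates the cause's past
#' from the effect's present (cause precedes effect).
#'
#' @param cause,effect Aligned numeric vectors or data frames on the same
#'   uniform grid, chronological order.
#' @param E,tau Embedding parameters (applied to the effect).
#' @param lib Optional integer vector of embedded-row indices forming the
#'   library; defaults to all usable rows.
#' @param tp Time displacement in steps (default 0).
#' @return List with `predictions` and `skill` (rho between estimated and
#'   observed cause values).
#' @export
cross_map_estimate <- function(cause, effect, E, tau = 1, lib = NULL, tp = 0) {
  cv <- series_values(cause); ev <- series_values(effect)
  if (length(cv) != length(ev)) abort("`cause` and `effect` must be aligned (equal length).")
  pr <- edm_predict(ev, cv, E, tau, tp, lib = lib)
  list(predictions = pr, skill = skill_cor(pr$observed, pr$predicted))
}

#' CCM convergence curve
#'
#' Cross-map skill as a function of library length L. For each L,
#' `n_samples` random libraries (sampled without replacement within each
#' draw) give a distribution of skills; convergence — skill rising with L
#' — is the CCM signature distinguishing causation from correlation.
#'
#' @inheritParams cross_map_estimate
#' @param lib_sizes Increasing vector of library sizes; default 10
#'   log-spaced sizes from 20 to the usable length.
#' @param n_samples Random libraries per size (default 100).
#' @param seed Integer seed (draws are reproducible).
#' @param replace Draw libraries with replacement (bootstrap) instead.
#' @return A `ccm_curve` object: tibble of per-sample skills plus
#'   summary, with `tidy()`, `glance()` and `autoplot()` methods.
#' @export
ccm_convergence <- function(cause, effect, E, tau = 1, lib_sizes = NULL,
                            n_samples = 100, tp = 0, seed = 1,
                            replace = FALSE) {
  cv <- series_values(cause); ev <- series_values(effect)
  n_emb <- length(ev) - (E - 1) * tau
  if (is.null(lib_sizes)) {
    lib_sizes <- unique(round(exp(seq(log(20), log(n_emb), length.out = 10))))
  }
  lib_sizes <- sort(unique(as.integer(lib_sizes)))
  if (any(lib_sizes < E + 2)) abort("library sizes must be at least E + 2.")
  if (max(lib_sizes) > n_emb) abort("largest library size exceeds the usable length.")
  et <- embed_target(ev, cv, E, tau, tp)
  samples <- with_seed(seed, {
    purrr::map_dfr(lib_sizes, function(L) {
      sk <- vapply(seq_len(n_samples), function(s) {
        lib <- if (replace) unique(sample.int(n_emb, L, replace = TRUE))
               else sample.int(n_emb, L)
        et_skill(et, lib)
      }, numeric(1))
      tibble::tibble(lib_size = L, sample = seq_len(n_samples), skill = sk)
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(samples, .data$lib_size),
    mean_skill = mean(.data$skill, na.rm = TRUE),
    q05 = quantile(.data$skill, 0.05, na.rm = TRUE, names = FALSE),
    q95 = quantile(.data$skill, 0.95, na.rm = TRUE, names = FALSE),
    .groups = "drop")
  structure(list(cause_label = ts_label(cause, "cause"),
                 effect_label = ts_label(effect, "effect"),
                 E = E, tau = tau, tp = tp, seed = seed,
                 samples = samples, summary = summary),
            class = "ccm_curve")
}

#' @export
print.ccm_curve <- function(x, ...) {
  cat(sprintf("CCM convergence: %s (cause) cross-mapped from %s (effect), E=%d tau=%d\n",
              x$cause_label, x$effect_label, x$E, x$tau))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ccm_curve <- function(x, ...) x$summary

#' @export
glance.ccm_curve <- function(x, ...) {
  s <- x$summary
  tibble::tibble(E = x$E, tau = x$tau, tp = x$tp,
                 lib_max = max(s$lib_size),
                 skill_at_lib_max = s$mean_skill[which.max(s$lib_size)],
                 skill_at_lib_min = s$mean_skill[which.min(s$lib_size)])
}
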