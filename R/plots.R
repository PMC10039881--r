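#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_point geom_col
#'   geom_vline geom_hline labs facet_wrap theme_minimal geom_tile
#'   scale_fill_viridis_c
NULL

#' Plot a CCM convergence curve
#'
#' @param object A `ccm_curve`.
#' @param bands Optional envelope bands from [envelope_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccm_curve <- function(object, bands = NULL, ...) {
  s <- object$summary
  p <- ggplot(s, aes(x = .data$lib_size, y = .data$mean_skill)) +
    geom_ribbon(aes(ymin = .data$q05, ymax = .data$q95), alpha = 0.2) +
    geom_line(linewidth = 0.8, colour = "#2166ac") +
    labs(x = "library size L", y = "cross-map skill ρ",
         title = sprintf("%s estimated from %s (E=%d, τ=%d)",
                         object$cause_label, object$effect_label,
                         object$E, object$tau)) +
    theme_minimal()
  if (!is.null(bands)) {
    p <- p + geom_ribbon(data = bands$bands,
                         aes(x = .data$lib_size, ymin = .data$lower,
                             ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.25, fill = "#b2182b")
  }
  p
}

#' Plot a time-delayed CCM profile
#'
#' @param object A `delayed_ccm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delayed_ccm <- function(object, ...) {
  g <- object$profile
  ggplot(g, aes(x = .data$tp, y = .data$smoothed)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.2) +
    geom_line(colour = "#2166ac") +
    geom_point(data = dplyr::summarise(
      dplyr::group_by(object$samples, .data$tp),
      skill = mean(.data$skill, na.rm = TRUE)),
      aes(y = .data$skill), size = 0.8) +
    geom_vline(xintercept = object$optimal_tp, linetype = 2) +
    labs(x = "time displacement tp (steps)", y = "cross-map skill ρ",
         title = sprintf("%s from %s: optimal tp = %+d",
                         object$cause_label, object$effect_label,
                         object$optimal_tp)) +
    theme_minimal()
}

#' Plot a threshold-response (regime) fit
#'
#' Cross-plot with 2-D density shading, the fitted step-like curve, and
#' the estimated threshold.
#'
#' @param object A `regime_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regime_model <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_bin2d(bins = 40) +
    scale_fill_viridis_c(option = "G", direction = -1) +
    geom_line(data = object$grid, aes(y = .data$fitted),
              colour = "#2166ac", linewidth = 1) +
    geom_vline(xintercept = object$x_star, linetype = 2) +
    geom_hline(yintercept = c(35, 65), linetype = 3) +
    labs(x = "precipitation proxy", y = "forest cover (%)",
         title = sprintf("threshold x* = %.2f", object$x_star)) +
    theme_minimal()
}

#' Plot a red-noise spectrum with significance curves
#'
#' @param object A `spectral_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_result <- function(object, ...) {
  tb <- tidyr::pivot_longer(object$table, c("p80", "p90", "p95"),
                            names_to = "level", values_to = "threshold")
  ggplot(object$table, aes(x = .data$freq, y = .data$power)) +
    geom_line() +
    geom_line(data = tb, aes(y = .data$threshold, colour = .data$level),
              linetype = 2) +
    labs(x = "frequency (1/kyr)", y = "bias-corrected power",
         colour = "MC level") +
    theme_minimal()
}

#' Plot an evolutive (sliding-window) spectrum
#'
#' @param object An `evolutive_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evolutive_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$center, y = .data$freq,
                     fill = .data$power)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "window center (depth or age)", y = "frequency (cycles/unit)") +
    theme_minimal()
}

#' Plot rolling correlations with significance shading
#'
#' @param data Output of [rolling_correlation()].
#' @return A ggplot faceted by window size.
#' @export
plot_rolling_correlation <- function(data) {
  ggplot(data, aes(x = .data$age, y = .data$r)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.2) +
    geom_line(aes(colour = .data$significant, group = 1)) +
    facet_wrap(~window, labeller = ggplot2::label_both) +
    labs(x = "age (kyr BP)", y = "rolling Pearson r") +
    theme_minimal()
}
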