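#' Surrogate ensembles for significance testing
#'
#' Null series preserving the autocorrelation structure of the source:
#' `"circular-shift"` rotates the series by a random offset in
#' \[n/10, 9n/10\] (exact value multiset and full autocorrelation
#' preserved); `"fourier-phase"` randomizes Fourier phases while keeping
#' the amplitude spectrum (mean and variance preserved).
#'
#' @param x Numeric vector or data frame (uniform grid, no missing values).
#' @param n Number of surrogates (default 100).
#' @param method `"circular-shift"` or `"fourier-phase"`.
#' @param seed Integer seed.
#' @return List with `surrogates` (matrix, one column per surrogate),
#'   `method` and `seed`.
#' @export
make_surrogates <- function(x, n = 100,
                            method = c("circular-shift", "fourier-phase"),
                            seed = 1) {
  method <- match.arg(method)
  v <- series_values(x)
  if (n < 2) abort("need at least 2 surrogates.")
  len <- length(v)
  surr <- with_seed(seed, {
    if (method == "circular-shift") {
      offs <- sample(seq(floor(len / 10), ceiling(9 * len / 10)), n, replace = TRUE)
      vapply(offs, function(k) v[(seq_len(len) + k - 1) %% len + 1], numeric(len))
    } else {
      z <- fft(v)
      vapply(seq_len(n), function(i) {
        amp <- Mod(z)
        ph <- runif(len, 0, 2 * pi)
        ph[1] <- Arg(z)[1]                       # keep the mean (DC term)
        half <- seq(2, ceiling((len + 1) / 2))
        zz <- complex(modulus = amp, argument = ph)
        # enforce conjugate symmetry so the inverse transform is real
        if (len %% 2 == 0) {
          zz[len / 2 + 1] <- complex(modulus = amp[len / 2 + 1],
                                     argument = if (runif(1) < 0.5) 0 else pi)
          sym <- seq(2, len / 2)
        } else sym <- half
        zz[len + 2 - sym] <- Conj(zz[sym])
        Re(fft(zz, inverse = TRUE)) / len
      }, numeric(len))
    }
  })
  list(surrogates = surr, method = method, seed = seed, n = n, source_n = len)
}

#' Surrogate envelope test on a CCM convergence curve
#'
#' The real curve passes when its mean skill at the largest library size
#' exceeds the upper surrogate percentile there; per-L percentile bands
#' are returned for plotting.
#'
#' @param real A `ccm_curve` for the real pair.
#' @param surrogate_skills Matrix or data frame of surrogate skills: one
#'   row per library size of `real`, one column per surrogate (or a
#'   vector of surrogate skills at the largest L only).
#' @param percentiles Lower/upper band percentiles (default 5 and 95).
#' @return List with `pass`, `bands` (tibble `lib_size`, `lower`,
#'   `upper`) and the observed terminal skill.
#' @export
envelope_test <- function(real, surrogate_skills, percentiles = c(5, 95)) {
  stopifnot(inherits(real, "ccm_curve"))
  s <- real$summary
  if (is.vector(surrogate_skills) && is.null(dim(surrogate_skills))) {
    surrogate_skills <- matrix(surrogate_skills, nrow = 1)
    lib <- max(s$lib_size)
  } else {
    surrogate_skills <- as.matrix(surrogate_skills)
    if (nrow(surrogate_skills) != nrow(s)) {
      abort("surrogate skills must have one row per library size of `real`.")
    }
    lib <- s$lib_size
  }
  p <- percentiles / 100
  bands <- tibble::tibble(
    lib_size = lib,
    lower = apply(surrogate_skills, 1, quantile, p[1], na.rm = TRUE, names = FALSE),
    upper = apply(surrogate_skills, 1, quantile, p[2], na.rm = TRUE, names = FALSE))
  rho_max <- s$mean_skill[which.max(s$lib_size)]
  pass <- rho_max > bands$upper[which.max(bands$lib_size)]
  list(pass = pass, bands = bands, skill_at_lib_max = rho_max)
}

#' Rank-based ROC area under the curve
#'
#' The probability that a randomly chosen real skill exceeds a randomly
#' chosen surrogate skill, with half credit for ties — computed exactly
#' from the rank statistic and equal to the trapezoidal ROC area.
#'
#' @param real_skills,surrogate_skills Non-empty numeric vectors (e.g.
#'   skills of the top-5 embedding combinations vs surrogate skills).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8), c(0.85, 0.1))  # 0.75
roc_auc <- function(real_skills, surrogate_skills) {
  real_skills <- real_skills[is.finite(real_skills)]
  surrogate_skills <- surrogate_skills[is.finite(surrogate_skills)]
  n_r <- length(real_skills); n_s <- length(surrogate_skills)
  if (n_r == 0 || n_s == 0) abort("both skill sets must be non-empty.")
  r <- rank(c(real_skills, surrogate_skills), ties.method = "average")
  (sum(r[seq_len(n_r)]) - n_r * (n_r + 1) / 2) / (n_r * n_s)
}

#' Classify a causal association from envelope and AUC evidence
#'
#' An association counts as causal only when the real curve escapes the
#' surrogate envelope AND the ROC separation is strong: class
#' `"significant"` for AUC > 0.9, `"weak"` for 0.8 < AUC <= 0.9, and
#' `"none"` otherwise (including any envelope failure, whatever the AUC).
#'
#' @param envelope_pass Logical from [envelope_test()].
#' @param auc AUC from [roc_auc()].
#' @param direction Optional direction ruling from [direction_verdict()];
#'   a `"ruled-out"` ruling (positive optimal displacement — the effect
#'   predicts the candidate cause's future) downgrades the final class to
#'   `"none"` whatever the AUC, because strong unidirectional coupling
#'   leaks skill into the reverse cross-map that only the time-delayed
#'   analysis can disqualify. The AUC-only class is kept as `auc_class`.
#' @param pair Optional c(cause, effect) labels.
#' @param optimal_tp Optional named numeric of both directions' optima.
#' @return A `causal_verdict` object (list with `class`, `auc_class`,
#'   `auc`, `envelope_pass`, `direction`, labels); has a `tidy()` method.
#' @export
classify_causality <- function(envelope_pass, auc, direction = NULL,
                               pair = c(cause = "A", effect = "B"),
                               optimal_tp = NULL) {
  auc_class <- if (!isTRUE(envelope_pass)) "none"
               else if (auc > 0.9) "significant"
               else if (auc > 0.8) "weak"
               else "none"
  cls <- if (!is.null(direction) && identical(direction, "ruled-out")) "none"
         else auc_class
  structure(list(cause = pair[[1]], effect = pair[[2]], class = cls,
                 auc_class = auc_class, auc = auc,
                 envelope_pass = isTRUE(envelope_pass),
                 direction = direction, optimal_tp = optimal_tp),
            class = "causal_verdict")
}

#' @export
print.causal_verdict <- function(x, ...) {
  cat(sprintf("%s -> %s: %s (AUC %.3f, envelope %s%s)\n", x$cause, x$effect,
              x$class, x$auc, if (x$envelope_pass) "pass" else "fail",
              if (!is.null(x$direction)) paste0(", direction ", x$direction) else ""))
  invisible(x)
}

#' @export
tidy.causal_verdict <- function(x, ...) {
  tibble::tibble(cause = x$cause, effect = x$effect, class = x$class,
                 auc_class = x$auc_class %||% x$class,
                 auc = x$auc, envelope_pass = x$envelope_pass,
                 direction = x$direction %||% NA_character_,
                 tp_forward = (x$optimal_tp %||% c(NA_real_))[1],
                 tp_reverse = (x$optimal_tp %||% c(NA_real_, NA_real_))[2])
}

#' Time-delayed CCM profile
#'
#' Cross-map skill as a function of the time displacement `tp` between
#' the effect's embedding and the cause states being estimated. For each
#' tp in `tp_range`, `n_boot` bootstrapped libraries of size `lib_size`
#' yield skill samples; a local quadratic smoother (span covering the
#' full grid) locates the optimal displacement, with edge values
#' (|tp| >= `edge_exclude`) excluded from the argmax because the smoother
#' is unreliable there. A negative optimum (cause leading the effect)
#' supports real causality; a positive optimum rules it out.
#'
#' @inheritParams cross_map_estimate
#' @param tp_range Displacement range in steps (default -10:10, 1 kyr
#'   steps in the paleo use case).
#' @param n_boot Bootstrap libraries per tp (default 100).
#' @param lib_size Library size per draw (default 100).
#' @param edge_exclude |tp| at and beyond which the smoothed curve is not
#'   considered for the optimum (default 9).
#' @param seed Integer seed.
#' @return A `delayed_ccm` object with the per-tp skills, the smoothed
#'   curve with a 95% band, and `optimal_tp`.
#' @export
delayed_ccm_profile <- function(cause, effect, E, tau = 1, tp_range = -10:10,
                                n_boot = 100, lib_size = 100,
                                edge_exclude = 9, seed = 1) {
  cv <- series_values(cause); ev <- series_values(effect)
  n_emb <- length(ev) - (E - 1) * tau
  if (lib_size + (E - 1) * tau + max(abs(tp_range)) > length(ev)) {
    abort("series too short for the requested library size and tp range.")
  }
  tp_range <- sort(unique(as.integer(tp_range)))
  samples <- with_seed(seed, {
    purrr::map_dfr(tp_range, function(tp) {
      et <- embed_target(ev, cv, E, tau, tp)
      sk <- vapply(seq_len(n_boot), function(b) {
        lib <- unique(sample.int(n_emb, lib_size, replace = TRUE))
        et_skill(et, lib)
      }, numeric(1))
      tibble::tibble(tp = tp, boot = seq_len(n_boot), skill = sk)
    })
  })
  fit <- loess(skill ~ tp, data = samples, degree = 2, span = 1,
               family = "gaussian")
  grid <- tibble::tibble(tp = tp_range)
  pr <- predict(fit, newdata = grid, se = TRUE)
  grid$smoothed <- as.numeric(pr$fit)
  grid$lower <- grid$smoothed - 1.96 * pr$se.fit
  grid$upper <- grid$smoothed + 1.96 * pr$se.fit
  considered <- abs(grid$tp) < edge_exclude
  opt <- grid$tp[considered][which.max(grid$smoothed[considered])]
  structure(list(cause_label = ts_label(cause, "cause"),
                 effect_label = ts_label(effect, "effect"),
                 E = E, tau = tau, n_boot = n_boot, lib_size = lib_size,
                 seed = seed, samples = samples, profile = grid,
                 considered = considered, optimal_tp = opt),
            class = "delayed_ccm")
}

#' @export
print.delayed_ccm <- function(x, ...) {
  cat(sprintf("Delayed CCM: %s estimated from %s; optimal tp = %+d steps\n",
              x$cause_label, x$effect_label, x$optimal_tp))
  invisible(x)
}

#' @export
tidy.delayed_ccm <- function(x, ...) {
  dplyr::mutate(x$profile, considered = x$considered)
}

#' @export
glance.delayed_ccm <- function(x, ...) {
  tibble::tibble(optimal_tp = x$optimal_tp, E = x$E, tau = x$tau,
                 max_smoothed_skill = max(x$profile$smoothed[x$considered]))
}

#' Direction ruling from a pair of delayed-CCM profiles
#'
#' A positive optimal displacement means the effect predicts the
#' candidate cause's *future* — causality ruled out. A non-positive
#' optimum within `near_zero_band` of zero supports causality provided
#' the two directions' optima are asymmetric; symmetric near-zero optima
#' suggest synchrony (both variables driven by a third).
#'
#' @param profile_ab `delayed_ccm` for estimating A from B (A -> B tested).
#' @param profile_ba `delayed_ccm` for the reverse direction.
#' @param near_zero_band Steps counted as "near zero" (default 1).
#' @return List with `ruling` (`"causal"`, `"ruled-out"`,
#'   `"synchrony-suspected"`), both optima and the asymmetry.
#' @export
direction_verdict <- function(profile_ab, profile_ba, near_zero_band = 1) {
  t_ab <- profile_ab$optimal_tp
  t_ba <- profile_ba$optimal_tp
  asym <- abs(t_ab - t_ba)
  ruling <- if (t_ab > near_zero_band) "ruled-out"
            else if (abs(t_ab) <= near_zero_band && abs(t_ba) <= near_zero_band &&
                     asym <= near_zero_band) "synchrony-suspected"
            else "causal"
  list(ruling = ruling, tp_ab = t_ab, tp_ba = t_ba, asymmetry = asym,
       near_zero_band = near_zero_band)
}

#' Age-model sensitivity of a causal verdict
#'
#' Re-runs the full pair analysis with the first series' chronology
#' shifted by each `delta` (default -5, 0, +5 kyr, the age-model error
#' bound) and reports whether the verdict class is stable across shifts.
#'
#' @param cause,effect Series data frames (native grids; regridded
#'   internally per `config`).
#' @param config A [ccm_config()] list.
#' @param deltas Chronology shifts in kyr.
#' @param delayed Compute delayed profiles per shift (passed to
#'   [run_pair()]).
#' @return List with `verdicts` (tibble, one row per shift) and `stable`.
#' @export
sensitivity_age_shift <- function(cause, effect, config = ccm_config(),
                                  deltas = c(-5, 0, 5), delayed = TRUE) {
  runs <- purrr::map(deltas, function(d) {
    run_pair(shift_chronology(cause, d), effect, config = config,
             delayed = delayed)
  })
  verdicts <- dplyr::bind_rows(
    purrr::map2(runs, deltas,
                ~ dplyr::mutate(tidy(.x$verdict), delta = .y, .before = 1)))
  list(verdicts = verdicts, stable = length(unique(verdicts$class)) == 1,
       runs = runs)
}
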