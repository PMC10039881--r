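---
title: "Causal inference and regime-shift analysis for paleoecological time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal inference and regime-shift analysis for paleoecological time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(paleoccm)
```

## The scientific problem

Long proxy records — tree-pollen percentages from a peatland core, an
XRF-derived log(Ca/Fe) moisture proxy, ice-core greenhouse-gas series —
are correlated with one another for many reasons: shared orbital
forcing, common low-frequency trends, or genuine causal influence. The
questions this package answers are (i) *which* of those associations
are causal and in which direction, and (ii) whether an ecosystem
responds to its driver smoothly or through abrupt shifts between
alternative stable states separated by a threshold.

The causal machinery is empirical dynamic modeling. If a variable $X$
forces a variable $Y$ in a (possibly noisy) dynamical system, Takens'
theorem implies that the delay-coordinate reconstruction of $Y$ — the
"shadow manifold" built from vectors
$(y_t, y_{t-\tau}, \ldots, y_{t-(E-1)\tau})$ — embeds the states of
$X$. Convergent cross-mapping (CCM) exploits this: $X$ is estimated
from the nearest neighbours of $Y$'s manifold, and the Pearson
correlation $\rho$ between estimated and observed $X$ (the "CCM
skill") *converges upward* as the library of manifold points grows.
Convergence with library size is what separates causality from mere
correlation.

## The pipeline, stage by stage

### Regridding and chronology handling

All pairwise analyses run on series linearly interpolated to an
equidistant grid (1 kyr by default, `ccm_config(step = )`). Two
conventions matter:

* **Ages are kyr BP**, larger = older. Before any embedding the
  aligned block is reversed into chronological order so that a
  positive forecast horizon means "toward the present".
* **Gaps are never bridged.** Grid points falling inside a sampling
  gap wider than five times the median native spacing are marked
  missing (`to_uniform_grid(max_gap_factor = 5)`), and the embedding
  stages consume only the longest contiguous non-missing block.
  Interpolating across a hiatus would fabricate dynamics exactly where
  the cross-map looks for them.

`shift_chronology()` applies constant age offsets; verdicts are
re-derived under ±5 kyr shifts (`sensitivity_age_shift()`) because
that is the age-model uncertainty a tuned peatland chronology
realistically carries.

### Simplex projection and parameter selection

Forecast skill of simplex projection (E+1 nearest neighbours, weights
$w_i = e^{-d_i/d_{\min}}$, leave-one-out) selects the embedding: an
exhaustive scan over $E \in [1,10]$, $\tau \in [1,4]$, ranked by
$\rho$, ties broken toward the smaller (more parsimonious) $E$ and
$\tau$. Numerical conventions, all deliberately deterministic:

* neighbour ties in distance are broken by earlier time index;
* if a neighbour sits at distance exactly zero, the zero-distance
  neighbours take all the weight (the standard simplex convention);
* only the target vector itself is excluded from the library — no
  Theiler window, because at 1 kyr spacing successive samples are
  already dynamically distant.

### Significance: surrogates, envelope, AUC

A cross-map skill means nothing by itself; serially correlated series
cross-map each other spuriously. Two null models are provided
(`make_surrogates()`):

* **circular-shift** (default): the candidate cause rotated by a
  random offset in $[n/10, 9n/10]$. Preserves the full
  autocorrelation and value distribution exactly; destroys only the
  temporal pairing.
* **fourier-phase**: amplitude spectrum kept, phases randomized.
  Exposed because "phase-shifted surrogate" is ambiguous in the
  literature; the method used is recorded in every output.

Significance is then assessed twice, and *both* checks must pass
(`classify_causality()`):

1. **Envelope**: the real convergence curve at the largest library
   size must exceed the 95th percentile of 100 surrogate skills.
2. **ROC/AUC**: real skills from the five best $(E,\tau)$
   combinations are pooled against the corresponding surrogate skills
   and summarized as the area under the ROC curve, computed exactly
   from the rank statistic. AUC > 0.9 → *significant*; 0.8–0.9 →
   *weak*; otherwise *none*. Pooling (rather than averaging per-combo
   AUCs) uses every skill value as one observation of the separation;
   per-combo values remain available from the returned skill sets.

### Time-delayed cross-mapping and direction

CCM alone over-detects in strongly coupled systems: if $X$ drives
$Y$ hard, the skill of "estimating $Y$ from $X$'s manifold" is also
elevated, because $Y$ is partly a function of $X$'s recent history.
The time-delayed analysis resolves this. `delayed_ccm_profile()`
evaluates the cross-map at displacements $t_p \in [-10, 10]$ (100
bootstrapped libraries of size 100 per displacement), smooths skill
against $t_p$ with a local quadratic (span covering the whole grid)
and takes the argmax of the smoothed curve, excluding $|t_p| \ge 9$
where the smoother is edge-biased.

Sign convention: **negative $t_p$ estimates the candidate cause's
past** from the effect's present embedding. A genuine cause precedes
its effect, so a real causal link shows a negative-but-near-zero
optimum, while a *positive* optimum — the effect predicting the
cause's future — rules causality out. `direction_verdict()` encodes
this: ruled-out for optima beyond the near-zero band (1 step), synchrony
suspected when both directions peak symmetrically at zero, causal
otherwise. A ruled-out direction downgrades the final class to
*none* regardless of its AUC; integrating the displacement evidence
into the verdict is what lets the pipeline reject the spurious
reverse direction of a strongly one-way coupled system (the package's
acceptance tests exercise exactly this on coupled logistic maps).

### Regime detection

`fit_threshold_response()` fits forest cover against the moisture
proxy with a penalized cubic regression spline (`mgcv::gam`, basis
`"cr"`, `k = 25`, smoothness by GCV). From the fit on a 1000-point
grid it extracts:

* the **threshold** $x^\*$ = argmax of the finite-difference
  derivative (with a mid-level-crossing alternative reported
  alongside, since "the threshold" has no unique estimator);
* **plateau levels** = mean fit over the outer deciles of $x$;
* **prevalence bands** = the $x$ below/above which ≥90 % of
  observations fall in one regime — an operationalization of
  "steppe dominates below, forest prevails above";
* an **unreliable flag** when the derivative peaks at the support
  edge or is near-constant (a linear response has no threshold).

`binned_histograms()` makes the bimodality visible: within bins of
the proxy, both regime modes (below 35 %, above 65 % tree pollen)
must each hold ≥10 % of the bin mass for the bin to be flagged
bimodal. `classify_regime()` applies the 35/65 cut-offs;
`conditional_subset()` restricts a cross-plot to intervals where a
conditioning series (e.g. ice-core CO₂ ≥ 260 ppmv) holds.

### Supporting statistics

* `rolling_correlation()`: windowed Pearson r (20–50 steps by 10),
  two-sided 95 % significance from phase-randomized surrogate pairs.
* `pca_unit_variance()`: SVD of the centered, unit-variance element
  matrix; loading signs fixed so each component's dominant loading is
  positive.
* `rednoise_spectrum()`: Lomb–Scargle periodogram on the *native*
  (uneven) grid against an AR(1) null whose persistence time is
  estimated by maximum likelihood of an exponential-decay
  autocovariance (an Ornstein–Uhlenbeck model, so uneven spacing is
  handled exactly); 1000 Monte-Carlo AR(1) realizations simulated on
  the same time grid give 80/90/95 % percentile curves, and the
  spectrum is bias-corrected by the null mean. The lag-1 moment
  estimate is the fallback when the likelihood optimization
  degenerates.
* `evolutive_spectrum()`: sliding sine-tapered FFT spectra along a
  depth axis (default 0.01 m resample step), for tracking cycle
  wavelengths through a sediment column.

## The synthetic generators, and what they do not emulate

Every statistical guarantee is tested against generators whose causal
structure is known (`coupled_logistic()`, `simulate_paleo_system()`,
`simulate_element_counts()`), all seed-deterministic with their
ground truth returned alongside the data.

`simulate_paleo_system()` emulates the structure of a
glacial–interglacial proxy stack: quasi-orbital forcing (100/41/23
kyr sinusoids plus AR(1) noise), a precipitation proxy lagging the
forcing by 5 kyr, and a vegetation cover switching with hysteresis
between two regime levels (20 % and 80 %, switching thresholds ±0.3
on the standardized precipitation scale, 5 % observation noise). The
0.2 kyr base grid with uniform jitter emulates a ~200-yr sampling
resolution and forces the interpolation stage to do real work. What
it does **not** emulate: realistic spectral amplitudes, millennial
overprints, proxy-specific taphonomy, or age-model error other than
constant shifts — so passing tests demonstrate that the machinery
recovers known structure, not that any particular real-world verdict
is correct.

Two deliberate generator behaviours worth knowing:

* In `coupled_logistic()`, the $r = 3.5$ map is periodic (stable
  4-cycle) when uncoupled. Couple it *into* the chaotic $r = 3.8$
  map (`b_xy > 0`, with y autonomous) and the whole system can lock
  onto a periodic orbit on which every phase-shifted surrogate
  cross-maps perfectly — a degenerate case where CCM significance is
  undefined almost by construction. The detectability testbed
  therefore couples the chaotic map into the periodic one
  (`b_yx = 0.32`), which makes both series chaotic and the true
  direction x → y recoverable.
* `simulate_element_counts()` rescales its realized factor series to
  the exact specified variances, so the eigenstructure recorded in
  its truth object is exact rather than subject to sampling noise.

## Problem sizes and runtime choices

The shipped test-suite and acceptance script run the full protocol at
the sizes the method is designed for — maps of length 1000 with 100
surrogates and the complete E/τ scan, 40-replicate null calibrations
at n = 500, delayed profiles with 100×100 bootstrap — while keeping
Monte-Carlo side checks (spectral nulls, white-noise calibration) at
a few hundred draws, sizes at which their sampling error is already
far below the tested tolerances. The nearest-neighbour kernel is
compiled (C++), which is what makes exhaustive scans over surrogate
ensembles practical; it reproduces a naive R implementation of the
simplex rules to 10⁻¹⁰, ties included.

## Known limitations

* CCM presumes deterministic dynamics observed through noise; for
  linear stochastic systems the delayed-displacement evidence (sign
  and asymmetry) carries most of the directional information.
* Periodic or phase-locked systems defeat surrogate-based CCM
  significance (see above); the package reports such pairs as
  synchrony-suspected rather than causal when their displacement
  optima are symmetric.
* The envelope test checks the terminal library size only; a curve
  that escapes the envelope without rising is still reported, and the
  separate convergence check (skill at large vs small L) should be
  consulted.
* The threshold estimator inherits GAM smoothing bias: with GCV and
  k = 25 a true step is localized to a few hundredths of the proxy
  range, but heavily autocorrelated residuals can widen that.
* One verdict per ordered pair: confounding by an unobserved common
  driver appears as bidirectional "causality" with symmetric optima,
  which is flagged, not resolved.

## A worked synthetic example

```{r demo, eval = FALSE}
sys <- simulate_paleo_system(seed = 1)
cfg <- ccm_config(seed = 1)
pair <- run_pair(sys$precipitation, sys$vegetation, cfg)
pair$verdict
autoplot(pair$significance$curve, bands = pair$significance$envelope)
autoplot(pair$profiles$ab)

joint <- dplyr::inner_join(
  dplyr::rename(to_uniform_grid(sys$precipitation, 1), x = value),
  dplyr::rename(tibble::as_tibble(to_uniform_grid(sys$vegetation, 1)), y = value),
  by = "age")
rm <- fit_threshold_response(dplyr::filter(joint, is.finite(x), is.finite(y)))
glance(rm)
autoplot(rm)
```

The full synthetic reproduction — causal matrix over the three-series
chain, regime fit, spectra, and the recovery checks — is packaged as
`run_demo(seed)`.
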