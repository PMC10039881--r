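# O(n) centered rolling Pearson correlation via cumulative sums.
roll_cor <- function(x, y, w) {
  n <- length(x)
  if (w > n) abort("window exceeds series length.")
  cs <- function(v) c(0, cumsum(v))
  sx <- cs(x); sy <- cs(y); sxy <- cs(x * y); sxx <- cs(x^2); syy <- cs(y^2)
  i <- seq_len(n - w + 1)
  Sx <- sx[i + w] - sx[i]; Sy <- sy[i + w] - sy[i]
  Sxy <- sxy[i + w] - sxy[i]; Sxx <- sxx[i + w] - sxx[i]; Syy <- syy[i + w] - syy[i]
  num <- w * Sxy - Sx * Sy
  den <- sqrt(pmax(w * Sxx - Sx^2, 0) * pmax(w * Syy - Sy^2, 0))
  r <- ifelse(den > 0, num / den, NA_real_)
  center <- i + floor((w - 1) / 2)
  list(center = center, r = pmin(1, pmax(-1, r)))
}

#' Rolling correlation with surrogate significance
#'
#' Pearson correlation in centered rolling windows of several sizes
#' (default 20–50 steps in increments of 10, one step = 1 kyr on the
#' standard grid), with per-window two-sided 95% significance against
#' phase-randomized surrogate pairs.
#'
#' @param a,b Aligned series (data frames with `value` or numeric
#'   vectors) on an identical uniform grid.
#' @param windows Window sizes in steps.
#' @param n_surr Number of surrogate pairs (default 100).
#' @param method Surrogate method (default `"fourier-phase"`).
#' @param seed Integer seed.
#' @return Tibble with `window`, `center` (index), `age` when available,
#'   `r`, `lower`, `upper`, `significant`.
#' @export
rolling_correlation <- function(a, b, windows = seq(20, 50, 10),
                                n_surr = 100, method = "fourier-phase",
                                seed = 1) {
  av <- series_values(a); bv <- series_values(b)
  if (length(av) != length(bv)) abort("series must be aligned (equal length).")
  age <- if (is.data.frame(a)) a$age else seq_along(av)
  sa <- make_surrogates(av, n_surr, method, seed = derive_seed(seed, "rollcorr_a"))
  sb <- make_surrogates(bv, n_surr, method, seed = derive_seed(seed, "rollcorr_b"))
  purrr::map_dfr(windows, function(w) {
    real <- roll_cor(av, bv, w)
    surr <- matrix(vapply(seq_len(n_surr), function(s) {
      roll_cor(sa$surrogates[, s], sb$surrogates[, s], w)$r
    }, numeric(length(real$r))), nrow = length(real$r))
    lower <- apply(surr, 1, quantile, 0.025, na.rm = TRUE, names = FALSE)
    upper <- apply(surr, 1, quantile, 0.975, na.rm = TRUE, names = FALSE)
    tibble::tibble(window = w, center = real$center, age = age[real$center],
                   r = real$r, lower = lower, upper = upper,
                   significant = real$r < lower | real$r > upper)
  })
}

#' Unit-variance PCA of an element table
#'
#' Columns are centered and scaled to unit variance and decomposed by
#' SVD; loading signs are fixed so each component's largest-magnitude
#' loading is positive. Rows with missing cells are dropped with a
#' message.
#'
#' @param table Data frame; element columns selected via `elements`
#'   (default: all numeric columns except `depth`/`age`).
#' @param elements Optional character vector of element column names.
#' @return List with `loadings` (tibble: element x PC), `scores`,
#'   `variance_fraction` (sums to 1), and `dropped_rows`.
#' @export
pca_unit_variance <- function(table, elements = NULL) {
  if (is.null(elements)) {
    elements <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                        c("depth", "age"))
  }
  m <- as.matrix(table[, elements, drop = FALSE])
  keep <- complete.cases(m)
  if (!all(keep)) inform(sprintf("dropping %d rows with missing cells.", sum(!keep)))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) abort("need at least 2 complete rows.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance column(s): %s",
                  paste(elements[sds == 0], collapse = ", ")))
  }
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(p$rotation, 2, flip, "*")
  sco <- sweep(p$x, 2, flip, "*")
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(loadings = dplyr::bind_cols(tibble::tibble(element = elements),
                                   tibble::as_tibble(rot)),
       scores = tibble::as_tibble(sco),
       variance_fraction = vf,
       dropped_rows = which(!keep))
}
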