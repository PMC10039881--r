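#' Construct a proxy time-series tibble
#'
#' The universal currency of the pipeline is a two-column tibble with `age`
#' (kyr BP, strictly increasing — larger is older) and `value`. Metadata
#' (label, unit, whether the grid is uniform) travel as attributes; every
#' function in the package accepts any data frame with these two columns,
#' so metadata loss through dplyr verbs is harmless.
#'
#' @param age Numeric vector of ages in kyr BP.
#' @param value Numeric proxy values; `NA` marks explicitly missing points
#'   (never silently interpolated downstream).
#' @param label Free-text series label.
#' @param unit Unit string carried as metadata.
#' @return A tibble of class `paleo_ts` with columns `age` and `value`.
#' @export
#' @examples
#' paleo_ts(c(1, 2, 3), c(0.5, 0.7, 0.6), label = "demo")
paleo_ts <- function(age, value, label = "", unit = "") {
  if (length(age) != length(value)) {
    abort("`age` and `value` must have the same length.")
  }
  if (anyNA(age) || !is.numeric(age)) abort("`age` must be numeric and non-missing.")
  ord <- order(age)
  age <- age[ord]; value <- value[ord]
  if (any(diff(age) <= 0)) abort("ages must be strictly increasing (no duplicates).")
  out <- tibble::tibble(age = as.numeric(age), value = as.numeric(value))
  attr(out, "label") <- label
  attr(out, "unit") <- unit
  attr(out, "uniform") <- is_uniform(age)
  class(out) <- c("paleo_ts", class(out))
  out
}

ts_label <- function(ts, default = "") attr(ts, "label") %||% default

is_uniform <- function(age, tol = 1e-8) {
  if (length(age) < 3) return(TRUE)
  d <- diff(age)
  max(d) - min(d) <= tol * max(abs(d))
}

check_series <- function(data, arg = "data") {
  if (!is.data.frame(data) || !all(c("age", "value") %in% names(data))) {
    abort(sprintf("`%s` must be a data frame with `age` and `value` columns.", arg))
  }
  if (is.unsorted(data$age, strictly = TRUE)) {
    abort(sprintf("`%s$age` must be strictly increasing.", arg))
  }
  invisible(data)
}

# Values of the longest contiguous run of non-missing observations; the
# block the embedding stages consume (gaps are never bridged).
longest_contiguous <- function(data) {
  check_series(data)
  ok <- !is.na(data$value)
  if (!any(ok)) abort("series has no non-missing values.")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  dplyr::slice(tibble::as_tibble(data), starts[i]:ends[i])
}

#' Linearly regrid a series onto a uniform age grid
#'
#' Interpolates onto an equidistant grid from `ceiling(min(age))` to
#' `floor(max(age))` (CCM runs use 1 kyr steps). No extrapolation: the grid
#' never leaves the data range. Grid points falling inside a sampling gap
#' wider than `max_gap_factor` times the local median spacing are marked
#' missing rather than interpolated, so hiatuses are never bridged.
#'
#' @param data Data frame with `age` and `value`.
#' @param step Grid step in kyr (default 1).
#' @param max_gap_factor Gap threshold as a multiple of the median native
#'   spacing; `Inf` disables gap masking.
#' @return A uniform-grid `paleo_ts`.
#' @export
#' @examples
#' to_uniform_grid(paleo_ts(c(0, 2), c(0, 1)), step = 1)
to_uniform_grid <- function(data, step = 1, max_gap_factor = 5) {
  check_series(data)
  if (step <= 0) abort("`step` must be positive.")
  keep <- !is.na(data$value)
  age <- data$age[keep]; value <- data$value[keep]
  if (length(age) < 2) abort("need at least two non-missing points.")
  span <- max(age) - min(age)
  if (step > span) abort("`step` exceeds the data span.")
  lo <- ceiling(min(age) / step) * step
  hi <- floor(max(age) / step) * step
  grid <- seq(lo, hi, by = step)
  out <- approx(age, value, xout = grid, method = "linear", ties = "mean")$y
  if (is.finite(max_gap_factor)) {
    gaps <- diff(age)
    med <- median(gaps)
    wide <- which(gaps > max_gap_factor * med)
    for (w in wide) {
      inside <- grid > age[w] & grid < age[w + 1]
      out[inside] <- NA_real_
    }
  }
  res <- tibble::tibble(age = grid, value = out)
  attr(res, "label") <- ts_label(data)
  attr(res, "unit") <- attr(data, "unit") %||% ""
  attr(res, "uniform") <- TRUE
  attr(res, "step") <- step
  class(res) <- c("paleo_ts", class(res))
  res
}

#' Shift a chronology by a constant offset
#'
#' Adds `delta` kyr to every age, leaving values untouched. Used for
#' age-model sensitivity runs (the chronology carries uncertainties of up
#' to about 5 kyr, so verdicts are re-derived under +/-5 kyr shifts).
#'
#' @inheritParams to_uniform_grid
#' @param delta Shift in kyr (positive = older).
#' @return The shifted series.
#' @export
shift_chronology <- function(data, delta) {
  check_series(data)
  out <- dplyr::mutate(tibble::as_tibble(data), age = .data$age + delta)
  for (a in c("label", "unit", "uniform", "step")) attr(out, a) <- attr(data, a)
  class(out) <- unique(c("paleo_ts", class(out)))
  out
}
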