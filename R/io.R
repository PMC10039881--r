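#' Read a two-column proxy time series
#'
#' Reads (age, value) records from CSV, TSV, or PANGAEA-style tab files (a
#' header block terminated by a line `*/`, then tab-separated columns).
#' The first two numeric columns are taken as age (kyr BP) and value; rows
#' are sorted ascending in age and duplicate ages are collapsed by their
#' mean with a warning.
#'
#' @param path File path.
#' @param dialect One of `"csv"`, `"tsv"`, `"pangaea-tab"`.
#' @param label Series label; defaults to the file name.
#' @return A `paleo_ts` tibble.
#' @export
read_timeseries <- function(path, dialect = c("csv", "tsv", "pangaea-tab"),
                            label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  offset <- 0L
  if (dialect == "pangaea-tab") {
    end <- which(trimws(lines) == "*/")
    if (length(end)) {
      offset <- end[1]
      lines <- lines[-seq_len(offset)]
    }
  }
  sep <- if (dialect == "csv") "," else "\t"
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("file contains no data rows.")
  fields <- strsplit(lines, sep, fixed = TRUE)
  # header row: first line whose first two fields are not both numeric
  first <- suppressWarnings(lapply(fields[[1]], as.numeric))
  has_header <- anyNA(unlist(first[seq_len(min(2, length(first)))]))
  if (has_header) {
    fields <- fields[-1]
    lines <- lines[-1]
    offset <- offset + 1L
  }
  if (any(lengths(fields) < 2)) abort("two numeric columns required")
  age <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(age))
  if (length(bad)) {
    abort(sprintf("unparseable rows at line(s): %s",
                  paste(bad + offset + 1L, collapse = ", ")))
  }
  if (anyDuplicated(age)) {
    warn("duplicate ages collapsed by mean.")
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(age = age, value = val), .data$age),
      value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    age <- agg$age; val <- agg$value
  }
  if (length(age) < 3) abort("fewer than 3 usable rows.")
  paleo_ts(age, val, label = label %||% basename(path))
}

#' Write a series as CSV with a JSON metadata sidecar
#'
#' @param data Series data frame.
#' @param path Output CSV path (`age_kyr_bp,value` header); a `.json`
#'   sidecar with label, unit and transform notes is written alongside.
#' @param notes Character vector appended to the sidecar transform log.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path, notes = character()) {
  check_series(data)
  out <- tibble::tibble(age_kyr_bp = data$age, value = data$value)
  readr::write_csv(out, path)
  meta <- list(label = ts_label(data), unit = attr(data, "unit") %||% "",
               n = nrow(data), transform_log = as.list(notes))
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Pollen percentages with a restricted terrestrial main sum
#'
#' Percentages follow the restricted main-sum convention used at sites
#' with over-represented wetland grasses and sedges: taxa in the
#' terrestrial main sum (arboreal and non-arboreal) are expressed as
#' `100 * count / main_sum`; over-represented or non-terrestrial taxa
#' (Cyperaceae, Poaceae, aquatics, spores, algae) are excluded from the
#' main sum and expressed as `100 * count / (main_sum + own count)`.
#' The arboreal share of the main sum is returned as `tree_pollen_pct`.
#'
#' @param counts Data frame: one row per sample, an id column (`age`
#'   and/or `depth`) plus one count column per taxon.
#' @param groups Named character vector mapping each taxon column to one
#'   of `"arboreal"`, `"non_arboreal"`, `"excluded"`.
#' @return Tibble of per-sample percentages plus `tree_pollen_pct`;
#'   samples whose main sum is zero get `NA` (flagged missing, never 0%).
#' @export
pollen_percentages <- function(counts, groups) {
  taxa <- names(groups)
  missing_cols <- setdiff(taxa, names(counts))
  if (length(missing_cols)) {
    abort(sprintf("taxa absent from counts: %s", paste(missing_cols, collapse = ", ")))
  }
  ok <- groups %in% c("arboreal", "non_arboreal", "excluded")
  if (!all(ok)) abort("groups must be 'arboreal', 'non_arboreal' or 'excluded'.")
  id_cols <- setdiff(names(counts), taxa)
  main_taxa <- taxa[groups %in% c("arboreal", "non_arboreal")]
  arboreal <- taxa[groups == "arboreal"]
  excluded <- taxa[groups == "excluded"]
  cm <- as.matrix(counts[, main_taxa, drop = FALSE])
  if (any(cm < 0, na.rm = TRUE)) abort("counts must be nonnegative.")
  main_sum <- rowSums(cm, na.rm = TRUE)
  zero <- main_sum == 0
  pct <- sweep(cm, 1, main_sum, "/") * 100
  pct[zero, ] <- NA_real_
  out <- tibble::as_tibble(counts[, id_cols, drop = FALSE])
  out <- dplyr::bind_cols(out, tibble::as_tibble(pct))
  for (tx in excluded) {
    v <- 100 * counts[[tx]] / (main_sum + counts[[tx]])
    v[zero] <- NA_real_
    out[[tx]] <- v
  }
  out$tree_pollen_pct <- rowSums(pct[, arboreal, drop = FALSE])
  out$tree_pollen_pct[zero] <- NA_real_
  out
}

#' Normalize an XRF count table to per-row fractions
#'
#' Each retained element is divided by the row total over retained
#' elements, so rows sum to one. Ag and Rh are excluded by default (their
#' signals come from the instrument's collimator and anode, not the
#' sediment).
#'
#' @param counts Data frame with id columns and element count columns.
#' @param exclude Element columns to drop before normalizing.
#' @param elements Element columns; defaults to all numeric non-id columns
#'   except `depth`/`age`.
#' @return Tibble of fractions; all-zero rows become `NA` rows.
#' @export
normalize_xrf <- function(counts, exclude = c("Ag", "Rh"), elements = NULL) {
  if (is.null(elements)) {
    elements <- setdiff(names(counts)[vapply(counts, is.numeric, TRUE)],
                        c("depth", "age"))
  }
  elements <- setdiff(elements, exclude)
  m <- as.matrix(counts[, elements, drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) abort("counts must be nonnegative.")
  tot <- rowSums(m, na.rm = TRUE)
  frac <- sweep(m, 1, tot, "/")
  frac[tot == 0, ] <- NA_real_
  id_cols <- setdiff(names(counts), c(elements, exclude))
  dplyr::bind_cols(tibble::as_tibble(counts[, id_cols, drop = FALSE]),
                   tibble::as_tibble(frac))
}

#' Elemental log-ratio series
#'
#' `log(a/b)` eliminates non-linear matrix effects and the constant-sum
#' constraint of normalized count data; the ratio is identical whether
#' computed from raw counts or normalized fractions. Base 10 by default
#' (the XRF literature's convention). Nonpositive inputs yield `NA`.
#'
#' @param data Data frame holding both element columns and an `age` or
#'   `depth` column used as the series index.
#' @param num,den Column names (strings or bare names) of numerator and
#'   denominator elements.
#' @param base Logarithm base, default 10.
#' @param index Index column, default `"age"` falling back to `"depth"`.
#' @return A `paleo_ts` (index column renamed `age`).
#' @export
log_ratio <- function(data, num, den, base = 10, index = NULL) {
  num <- rlang::as_name(rlang::ensym(num))
  den <- rlang::as_name(rlang::ensym(den))
  index <- index %||% intersect(c("age", "depth"), names(data))[1]
  if (is.na(index)) abort("no `age` or `depth` index column found.")
  a <- data[[num]]; b <- data[[den]]
  v <- ifelse(is.na(a) | is.na(b) | a <= 0 | b <= 0, NA_real_,
              log(a / b, base = base))
  paleo_ts(data[[index]], v, label = sprintf("log(%s/%s)", num, den))
}
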