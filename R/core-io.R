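#' Treatment design table
#'
#' Describes the transplant treatments of a simulated-overturn incubation:
#' which water mass supplied the microbial inoculum (whole, unfiltered water)
#' and which supplied the 0.2 um filtrate, together with the filtrate volume
#' fraction and the incubation temperature. The default table encodes the
#' classic three-treatment design: a surface control (S/S), surface cells in
#' deep filtrate (S/D), and deep cells in surface filtrate (D/S), each diluted
#' 70% with filtrate.
#'
#' @param codes Character vector of treatment codes.
#' @param inoculum_source,filtrate_source Character vectors, `"surface"` or
#'   `"deep"`, recycled against `codes`.
#' @param filtrate_fraction Volume fraction of 0.2 um filtrate in each bottle,
#'   in `[0, 1]` (default 0.70; the inoculum fraction is its complement).
#' @param incubation_temp Incubation temperature in degrees C.
#'
#' @return A tibble with one row per treatment and columns `treatment`,
#'   `inoculum_source`, `filtrate_source`, `filtrate_fraction`,
#'   `incubation_temp`.
#' @export
#' @examples
#' treatment_design()
treatment_design <- function(codes = c("S/S", "S/D", "D/S"),
                             inoculum_source = c("surface", "surface", "deep"),
                             filtrate_source = c("surface", "deep", "surface"),
                             filtrate_fraction = 0.70,
                             incubation_temp = c(30.0, 30.0, 21.8)) {
  if (any(filtrate_fraction < 0 | filtrate_fraction > 1)) {
    abort("`filtrate_fraction` must lie in [0, 1].")
  }
  if (anyDuplicated(codes)) abort("treatment codes must be unique.")
  tbl <- tibble(
    treatment = codes,
    inoculum_source = inoculum_source,
    filtrate_source = filtrate_source,
    filtrate_fraction = filtrate_fraction,
    incubation_temp = incubation_temp
  )
  bad <- !tbl$inoculum_source %in% c("surface", "deep") |
    !tbl$filtrate_source %in% c("surface", "deep")
  if (any(bad)) abort("inoculum/filtrate sources must be 'surface' or 'deep'.")
  tbl
}

ts_required_cols <- c("treatment", "bottle", "time_days", "analyte", "value", "unit")

#' Read and validate an incubation time series
#'
#' Reads a long-format delimited table of incubation measurements — one row
#' per (treatment, bottle, day, analyte) — and validates it: times must be
#' strictly increasing within each (treatment, bottle, analyte) series,
#' concentration/abundance values must be non-negative, and each analyte must
#' use a single unit. Rows violating the invariants trigger an error with
#' row-level diagnostics; nothing is silently dropped.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the
#'   extension) with columns `treatment`, `bottle`, `time_days`, `analyte`,
#'   `value`, `unit` and optionally `qc_flag`.
#' @return A validated tibble (an incubation series) with a `qc_flag` column
#'   (`"ok"`, `"contaminated"` or `"missing"`).
#' @seealso [write_timeseries()], [validate_timeseries()], [flag_doc_outliers()]
#' @export
read_timeseries <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_timeseries(raw)
}

#' Validate an incubation series data frame
#'
#' @param x A data frame with the [read_timeseries()] schema.
#' @return The validated tibble, with `qc_flag` filled in (`NA` values get
#'   `"missing"`, everything else defaults to `"ok"`).
#' @export
validate_timeseries <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(ts_required_cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("time-series table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(x$time_days) || !is.numeric(x$value)) {
    abort("`time_days` and `value` must be numeric.")
  }
  if (!"qc_flag" %in% names(x)) x$qc_flag <- "ok"
  x$qc_flag[is.na(x$qc_flag)] <- "ok"
  x$qc_flag[is.na(x$value)] <- "missing"
  bad_flag <- !x$qc_flag %in% c("ok", "contaminated", "missing")
  if (any(bad_flag)) {
    abort(paste0("invalid qc_flag values: ",
                 paste(unique(x$qc_flag[bad_flag]), collapse = ", ")))
  }
  neg <- which(!is.na(x$value) & x$value < 0)
  if (length(neg)) {
    abort(paste0("negative value(s) for concentration/abundance at row(s): ",
                 paste(head(neg, 10), collapse = ", ")))
  }
  if (any(!is.na(x$time_days) & x$time_days < 0)) {
    abort("`time_days` must be >= 0.")
  }
  dup <- x |>
    group_by(.data$treatment, .data$bottle, .data$analyte, .data$time_days) |>
    summarise(n = n(), .groups = "drop") |>
    filter(n > 1)
  if (nrow(dup)) {
    keys <- paste0("(", dup$treatment, ", ", dup$bottle, ", day ",
                   dup$time_days, ", ", dup$analyte, ")")
    abort(paste0("duplicate timepoint(s) within a series: ",
                 paste(head(keys, 10), collapse = "; ")))
  }
  multi_unit <- x |>
    group_by(.data$analyte) |>
    summarise(k = dplyr::n_distinct(.data$unit), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(multi_unit)) {
    abort(paste0("analyte(s) with more than one unit: ",
                 paste(multi_unit$analyte, collapse = ", ")))
  }
  x |>
    arrange(.data$treatment, .data$bottle, .data$analyte, .data$time_days)
}

#' Write an incubation series to disk
#'
#' Inverse of [read_timeseries()] up to column order and float formatting.
#'
#' @param series An incubation series tibble.
#' @param path Output path; `.tsv` extension writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  series <- validate_timeseries(series)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(series, path, progress = FALSE)
  } else {
    readr::write_csv(series, path, progress = FALSE)
  }
  invisible(path)
}

#' Flag contaminated DOC observations by the 90th-percentile rule
#'
#' Within each (treatment, bottle, analyte) series, values strictly greater
#' than the group's 90th percentile (sample quantile with linear interpolation
#' between closest ranks, `type = 7`) are flagged `"contaminated"`. Values are
#' never removed, only flagged; flags other than `"ok"` are left untouched, so
#' the filter is idempotent. Groups smaller than `min_group` are skipped with
#' a warning.
#'
#' This implements the bulk-DOC contamination screen used for incubation
#' samples drawn through shared lines, where occasional handling contamination
#' shows up as isolated high outliers.
#'
#' @param series An incubation series tibble (see [read_timeseries()]).
#' @param analyte Analyte label the rule applies to (default `"DOC"`).
#' @param percentile Percentile threshold in (0, 100); default 90.
#' @param min_group Minimum observations per group for the rule; default 5.
#' @param group_vars Character vector of grouping columns; default
#'   `c("treatment", "bottle")` (the analyte is always part of the grouping).
#' @return The series with updated `qc_flag`.
#' @export
#' @examples
#' ts <- tibble::tibble(
#'   treatment = "S/S", bottle = "A", time_days = 0:9, analyte = "DOC",
#'   value = 1:10, unit = "umol C L-1"
#' )
#' flag_doc_outliers(ts)  # only the value 10 (> 9.1) is flagged
flag_doc_outliers <- function(series, analyte = "DOC", percentile = 90,
                              min_group = 5,
                              group_vars = c("treatment", "bottle")) {
  series <- validate_timeseries(series)
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must lie strictly between 0 and 100.")
  }
  target <- analyte
  key <- do.call(paste, c(series[group_vars], list(sep = "\r")))
  for (g in unique(key[series$analyte == target])) {
    idx <- which(key == g & series$analyte == target &
                   series$qc_flag != "missing")
    if (length(idx) < min_group) {
      warn(paste0("group '", gsub("\r", "/", g), "' has fewer than ",
                  min_group, " observations; percentile rule skipped."))
      next
    }
    thr <- quantile(series$value[idx], probs = percentile / 100,
                    type = 7, names = FALSE)
    hit <- idx[series$value[idx] > thr & series$qc_flag[idx] == "ok"]
    series$qc_flag[hit] <- "contaminated"
  }
  series
}

#' Expected concentration under conservative two-end-member mixing
#'
#' For a bottle prepared by diluting whole seawater (the inoculum) with 0.2 um
#' filtrate from another depth, the conservative-mixing expectation for any
#' analyte is the volume-weighted average of the two end-members. Measured
#' start-of-experiment concentrations are compared against this expectation as
#' a set-up QC (measured DOC typically falls within a few percent of it).
#'
#' @param surface_value,deep_value End-member concentrations (same units).
#' @param filtrate_fraction Volume fraction of filtrate in `[0, 1]`.
#' @param filtrate_source `"surface"` or `"deep"`: which end-member supplied
#'   the filtrate (the inoculum comes from the other).
#' @return A one-row tibble with the end-members, fraction, sources and the
#'   `expected` concentration.
#' @export
#' @examples
#' # deep filtrate at 70%: 0.7 * 110.1 + 0.3 * 94.8
#' expected_mixture_concentration(94.8, 110.1, 0.7, "deep")
expected_mixture_concentration <- function(surface_value, deep_value,
                                           filtrate_fraction,
                                           filtrate_source = c("deep", "surface")) {
  filtrate_source <- match.arg(filtrate_source)
  if (!is.finite(surface_value) || !is.finite(deep_value)) {
    abort("end-member values must be finite.")
  }
  if (filtrate_fraction < 0 || filtrate_fraction > 1) {
    abort("`filtrate_fraction` must lie in [0, 1].")
  }
  filtrate_value <- if (filtrate_source == "deep") deep_value else surface_value
  inoculum_value <- if (filtrate_source == "deep") surface_value else deep_value
  expected <- filtrate_fraction * filtrate_value +
    (1 - filtrate_fraction) * inoculum_value
  tibble(
    surface_value = surface_value,
    deep_value = deep_value,
    filtrate_fraction = filtrate_fraction,
    filtrate_source = filtrate_source,
    expected = expected
  )
}
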