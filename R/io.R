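#' Read a gradient time series from disk
#'
#' Supports two dialects:
#' \describe{
#'   \item{`tabular_csv`}{a two-column CSV with header `time_ns,
#'     dvdl_kcal_mol`; the time column must be uniformly spaced (within
#'     1e-6 ns).}
#'   \item{`amber_mdout`}{an AMBER TI output file; instantaneous `DV/DL`
#'     values are extracted from the energy records in order, stopping at the
#'     final averages/fluctuations blocks. The sampling interval is not
#'     encoded in these records and must be supplied.}
#' }
#' With `dialect = "auto"` the file content decides: a `time_ns` header
#' selects CSV, a `DV/DL` tag selects mdout.
#'
#' @param path Path to the file.
#' @param dialect `"auto"`, `"tabular_csv"` or `"amber_mdout"`.
#' @param lambda_value Lambda value attached to the series. Default 0.
#' @param sampling_interval Sampling interval in ns; required for
#'   `amber_mdout`, and validated against the time column for CSV when given.
#' @return A [gradient_series()].
#' @export
read_series <- function(path, dialect = c("auto", "tabular_csv", "amber_mdout"),
                        lambda_value = 0, sampling_interval = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop(sprintf("empty file: %s", path), call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("time_ns", lines[1], fixed = TRUE)) {
      "tabular_csv"
    } else if (any(grepl("DV/DL", lines, fixed = TRUE))) {
      "amber_mdout"
    } else {
      stop(sprintf("cannot auto-detect dialect of %s; pass `dialect` explicitly",
                   path), call. = FALSE)
    }
  }
  switch(dialect,
         tabular_csv = .read_tabular_csv(path, lambda_value, sampling_interval),
         amber_mdout = .read_amber_mdout(lines, path, lambda_value,
                                         sampling_interval))
}

.read_tabular_csv <- function(path, lambda_value, sampling_interval) {
  df <- utils::read.csv(path)
  need <- c("time_ns", "dvdl_kcal_mol")
  if (!all(need %in% names(df))) {
    stop(sprintf("CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  t <- df$time_ns; v <- df$dvdl_kcal_mol
  if (!length(t)) stop("CSV contains no rows", call. = FALSE)
  if (any(!is.finite(v))) {
    stop(sprintf("non-finite gradient value at row %d", which(!is.finite(v))[1]),
         call. = FALSE)
  }
  if (length(t) >= 2L) {
    dt <- diff(t)
    bad <- which(abs(dt - dt[1]) > 1e-6)
    if (length(bad)) {
      stop(sprintf("nonuniform time spacing at row %d (dt %.6g vs %.6g ns)",
                   bad[1] + 1L, dt[bad[1]], dt[1]), call. = FALSE)
    }
    if (!is.null(sampling_interval) && abs(dt[1] - sampling_interval) > 1e-6) {
      stop("time column spacing disagrees with `sampling_interval`",
           call. = FALSE)
    }
    sampling_interval <- dt[1]
  } else if (is.null(sampling_interval)) {
    stop("single-row CSV needs an explicit `sampling_interval`", call. = FALSE)
  }
  gradient_series(v, sampling_interval, lambda_value = lambda_value,
                  start_time = t[1], label = basename(path))
}

.read_amber_mdout <- function(lines, path, lambda_value, sampling_interval) {
  if (is.null(sampling_interval)) {
    stop("amber_mdout records carry no timing; supply `sampling_interval` (ns)",
         call. = FALSE)
  }
  # Instantaneous records end where the summary blocks begin.
  avg <- grep("A V E R A G E S|R M S  F L U C T U A T I O N S", lines)
  if (length(avg)) lines <- lines[seq_len(avg[1] - 1L)]
  hits <- regmatches(lines,
                     regexpr("DV/DL\\s*=\\s*(-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)",
                             lines))
  vals <- as.numeric(sub("DV/DL\\s*=\\s*", "", unlist(hits)))
  if (!length(vals)) {
    stop(sprintf("no DV/DL records in %s: not a TI output", path),
         call. = FALSE)
  }
  if (any(!is.finite(vals))) stop("non-finite DV/DL value", call. = FALSE)
  gradient_series(vals, sampling_interval, lambda_value = lambda_value,
                  label = basename(path))
}

#' Write a gradient series as a two-column CSV
#'
#' @param series A [gradient_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "gradient_series"))
  df <- data.frame(time_ns = series_times(series),
                   dvdl_kcal_mol = series$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Strip non-serializable parts and order keys recursively so identical
# structures always serialize to identical bytes.
.canonicalize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .canonicalize)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    x
  } else if (is.function(x)) {
    NULL
  } else {
    x
  }
}

#' Write a run record or free energy result as canonical JSON
#'
#' Serializes with sorted keys and fixed number formatting so that two runs
#' with identical seeds produce byte-identical files. `NA` values (for
#' example an undefined JS distance) are written as `null`.
#'
#' @param record A `window_run_record`, `free_energy_result`,
#'   `convergence_report`, or any list of such components.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path) {
  cls <- class(record)[1]
  payload <- .canonicalize(unclass(record))
  payload$record_class <- cls
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read back a JSON record written by [write_record()]
#'
#' @param path Path to the JSON file.
#' @return The deserialized record as a list; the original class name is in
#'   `$record_class`.
#' @export
read_record <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Load a protocol configuration from a YAML file
#'
#' Recognised keys: `protocol` (preset name used as the starting point),
#' `initial_ns`, `additional_ns`, `n_windows`, `js_threshold`,
#' `min_decorrelated`, `soft_cap_ns`, `hard_cap_ns`, `n_bins`. Explicit keys
#' override the preset's values.
#'
#' @param path Path to a YAML file.
#' @return A [protocol_config()].
#' @export
load_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- if (!is.null(cfg$protocol)) protocol_preset(cfg$protocol) else NULL
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  protocol_config(
    name = pick("protocol", "custom"),
    initial_length = pick("initial_ns", base$initial_length),
    additional_length = pick("additional_ns", base$additional_length),
    n_windows = pick("n_windows", if (is.null(base)) 9 else base$n_windows),
    js_threshold = pick("js_threshold", 0.1),
    min_decorrelated = pick("min_decorrelated", 50),
    soft_cap = pick("soft_cap_ns", 6.5),
    hard_cap = pick("hard_cap_ns", 10.5),
    n_bins = pick("n_bins", 7)
  )
}
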