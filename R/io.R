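# Plain-text I/O: trace files (commented key=value header + index,counts
# records), JSON reports, and CSV event tables. No vendor formats.

trace_header_keys <- c(
  dwell_time_s = "dwell_time",
  duration_s = "duration",
  sample_flow_ml_s = "sample_flow",
  transport_efficiency = "transport_efficiency",
  calib_slope_counts_per_dwell_per_ng_ml = "calib_slope",
  calib_intercept_counts_per_dwell = "calib_intercept"
)

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a time trace to a plain-text file
#'
#' The format is a CSV with a comment-prefixed header: lines
#' `#key=value` carrying the acquisition settings (keys name their units
#' explicitly), then a `index,counts` column header and one record per
#' dwell window. [read_trace()] round-trips the file bit-exactly.
#'
#' @param trace A `time_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "time_trace"))
  s <- trace$settings
  header <- vapply(
    names(trace_header_keys),
    function(k) sprintf("#%s=%s", k, fmt_num(s[[trace_header_keys[[k]]]])),
    character(1)
  )
  lines <- c(
    header,
    "index,counts",
    sprintf("%d,%d", seq_along(trace$intensities), trace$intensities)
  )
  writeLines(lines, path)
  invisible(path)
}

parse_error <- function(path, line, msg) {
  spicpms_error(
    sprintf("%s: line %d: %s", path, line, msg),
    "spicpms_parse_error"
  )
}

#' Read a time trace written by [write_trace()]
#'
#' Parse failures (missing header keys, non-integer or negative counts,
#' record-count mismatch against the header) are errors naming the
#' offending line.
#'
#' @param path File path.
#' @return A `time_trace` with `settings` populated from the header and
#'   `truth = NULL`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    validation_error(sprintf("file not found: %s", path))
  }
  lines <- readLines(path)
  header <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- strsplit(sub("^#", "", lines[i]), "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      parse_error(path, i, "malformed header line (expected #key=value)")
    }
    header[[kv[1L]]] <- suppressWarnings(as.numeric(kv[2L]))
    if (is.na(header[[kv[1L]]])) {
      parse_error(path, i, sprintf("non-numeric value for key `%s`", kv[1L]))
    }
    i <- i + 1L
  }
  missing <- setdiff(names(trace_header_keys), names(header))
  if (length(missing)) {
    parse_error(path, max(i - 1L, 1L), sprintf(
      "missing header keys: %s", paste(missing, collapse = ", ")
    ))
  }
  if (i > length(lines) || lines[i] != "index,counts") {
    parse_error(path, i, "expected column header `index,counts`")
  }
  first_record <- i + 1L
  records <- lines[seq.int(first_record, length.out = length(lines) - i)]

  settings <- acquisition_settings(
    dwell_time = header$dwell_time_s,
    duration = header$duration_s,
    sample_flow = header$sample_flow_ml_s,
    transport_efficiency = header$transport_efficiency,
    calib_slope = header$calib_slope_counts_per_dwell_per_ng_ml,
    calib_intercept = header$calib_intercept_counts_per_dwell
  )
  expected <- n_windows(settings)
  if (length(records) != expected) {
    parse_error(path, length(lines), sprintf(
      "%d records found but header implies %d dwell windows",
      length(records), expected
    ))
  }

  counts <- integer(expected)
  for (j in seq_along(records)) {
    line_no <- first_record + j - 1L
    parts <- strsplit(records[j], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      parse_error(path, line_no, "expected `index,counts`")
    }
    val <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(val) || val != floor(val)) {
      parse_error(path, line_no, sprintf("non-integer count `%s`", parts[2L]))
    }
    if (val < 0) {
      parse_error(path, line_no, sprintf("negative count %d", as.integer(val)))
    }
    counts[j] <- as.integer(val)
  }
  structure(
    list(intensities = counts, settings = settings, truth = NULL),
    class = "time_trace"
  )
}

report_fields <- function(x) {
  UseMethod("report_fields")
}

#' @export
report_fields.quant_result <- function(x) {
  list(
    type = "quant_result",
    n_events = x$n_events,
    number_concentration = x$number_concentration,
    particulate_mass_concentration = x$particulate_mass_concentration,
    dissolved_concentration = x$dissolved_concentration,
    mean_diameter = x$mean_diameter,
    median_diameter = x$median_diameter,
    sd_diameter = x$sd_diameter,
    size_lod = x$size_lod,
    diameters = x$diameters,
    settings = unclass(x$settings)
  )
}

#' @export
report_fields.recovery_report <- function(x) {
  c(list(type = "recovery_report"), unclass(x))
}

#' @export
report_fields.linearity_result <- function(x) {
  c(list(type = "linearity_result"), unclass(x))
}

#' @export
report_fields.partition_result <- function(x) {
  c(list(type = "partition_result"), unclass(x))
}

#' @export
report_fields.default <- function(x) {
  if (inherits(x, c("acquisition_settings", "transport_efficiency",
                    "ionic_calibration"))) {
    return(unclass(x))
  }
  x
}

#' Write an analysis report
#'
#' `format = "json"` writes every field of the result (plus the package
#' version) at full numeric precision; numbers survive a
#' write/[read_report()] round trip to better than 1e-12. `format = "csv"`
#' writes the per-event table of a `quant_result` (window_index, raw, net,
#' mass_fg, diameter_nm).
#'
#' @param results A `quant_result`, `recovery_report`, `linearity_result`
#'   or `partition_result` — or a named list of such objects (JSON only).
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!inherits(results, "quant_result")) {
      validation_error("csv reports are event tables of a quant_result")
    }
    utils::write.csv(results$events, path, row.names = FALSE)
    return(invisible(path))
  }
  body <- if (inherits(results, c("quant_result", "recovery_report",
                                  "linearity_result", "partition_result"))) {
    report_fields(results)
  } else if (is.list(results)) {
    lapply(results, report_fields)
  } else {
    validation_error("unsupported report object")
  }
  payload <- list(
    package = "spicpms",
    version = as.character(utils::packageVersion("spicpms")),
    results = body
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path File path.
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    validation_error(sprintf("file not found: %s", path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
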