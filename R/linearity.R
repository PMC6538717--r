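# Counting-linearity analysis of a serial-dilution ladder: fit the
# theoretical count line, form the difference curve (theoretical minus
# detected), and report the critical detected-particle count above which
# coincidence breaks counting linearity.

#' Expected detected count under Poisson coincidence
#'
#' With particle arrivals Poisson-distributed over dwell windows, two or
#' more particles in one window are read as a single event, so the
#' expected number of detected events is the expected number of occupied
#' windows: `n_windows * (1 - exp(-true_count / n_windows))`.
#'
#' @param true_count Expected number of particle arrivals over the whole
#'   acquisition; vectorized.
#' @param n_windows Number of dwell windows.
#' @return Expected detected event count.
#' @export
#' @examples
#' expected_detected(547, 3000) # ~500
expected_detected <- function(true_count, n_windows) {
  if (!is.numeric(true_count) || anyNA(true_count) || any(true_count < 0)) {
    validation_error("`true_count` must be finite and non-negative")
  }
  check_number(n_windows, "n_windows", lower = 1, integer = TRUE)
  n_windows * (1 - exp(-true_count / n_windows))
}

#' Construct a dilution series of detected counts
#'
#' @param concentrations Prepared mass concentrations, pg/mL; strictly
#'   positive, length >= 4.
#' @param detected_counts Detected events per acquisition, same length.
#' @param n_windows Number of dwell windows per acquisition.
#' @return An object of class `dilution_series`, sorted by increasing
#'   concentration.
#' @export
dilution_series <- function(concentrations, detected_counts, n_windows) {
  check_numeric_vector(concentrations, "concentrations", min_length = 4L)
  if (any(concentrations <= 0)) {
    validation_error("`concentrations` must be strictly positive")
  }
  check_numeric_vector(detected_counts, "detected_counts", lower = 0,
                       min_length = 4L)
  check_number(n_windows, "n_windows", lower = 1, integer = TRUE)
  if (length(concentrations) != length(detected_counts)) {
    validation_error(
      "`concentrations` and `detected_counts` differ in length"
    )
  }
  if (any(detected_counts > n_windows)) {
    validation_error("detected counts cannot exceed the number of windows")
  }
  ord <- order(concentrations)
  structure(
    list(
      concentrations = concentrations[ord],
      detected_counts = detected_counts[ord],
      n_windows = as.integer(n_windows)
    ),
    class = "dilution_series"
  )
}

#' Build a dilution series by detecting events in simulated traces
#'
#' @param traces A list of `time_trace` objects carrying
#'   `truth$mass_conc_pg` (from [simulate_dilution_series()]).
#' @param params A [detection_params()] object.
#' @return A `dilution_series`.
#' @export
dilution_series_from_traces <- function(traces, params = detection_params()) {
  conc <- vapply(traces, function(tr) tr$truth$mass_conc_pg, numeric(1))
  counts <- vapply(
    traces,
    function(tr) detect_events(tr, params)$n_events,
    numeric(1)
  )
  dilution_series(conc, counts, n_windows(traces[[1L]]$settings))
}

# Index of the last sample before a detector-overload collapse. Under
# Poisson occupancy the detected count is non-decreasing in concentration
# (up to counting noise), but when particle events occupy so many windows
# that the iterative mean + k sigma background estimator can no longer
# shed them, the detected count collapses to a fraction of its true value.
# Counting noise cannot nearly halve a count of 150 or more, so a drop
# below 60% of a running maximum of at least 150 marks the collapse
# unambiguously; samples from there on are excluded from the analysis.
detector_valid_prefix <- function(series) {
  y <- series$detected_counts
  run_max <- cummax(y)
  bad <- which(run_max >= 150 & y < 0.6 * run_max)
  if (length(bad)) bad[1L] - 1L else length(y)
}

#' Fit the theoretical count line of a dilution series
#'
#' The theoretical line is the count-versus-concentration relationship in
#' the absence of coincidence: `theoretical = slope * concentration`. Two
#' estimators are provided.
#'
#' `method = "occupancy"` (default) fits the Poisson-occupancy saturation
#' model `detected = n * (1 - exp(-b * c))` to the whole ladder by a
#' binomial GLM with complementary log-log link and log-concentration
#' offset, and returns the linear-limit slope `n * b`. Pooling all samples
#' makes the slope estimate precise even when the low-concentration
#' solutions yield only a handful of counts, as they do on a serial ladder
#' spanning three orders of magnitude.
#'
#' `method = "linear"` is a zero-intercept least-squares fit over the
#' low-concentration region only (the lowest `low_region_fraction` of
#' concentrations by rank). It assumes nothing about the saturation shape,
#' but on single-trial ladders its slope carries the Poisson noise of the
#' few bottom-of-ladder counts; a residual check warns when the fitted
#' region already shows saturation curvature.
#'
#' @param series A [dilution_series()].
#' @param method `"occupancy"` or `"linear"`.
#' @param low_region_fraction Fraction of the ladder (lowest
#'   concentrations, by rank) used by the linear fit; at least 3 points.
#'   Default 0.25.
#' @return An object of class `theoretical_line`: `slope` (counts per
#'   (pg/mL)), `method`, `low_region_max_conc`, `curvature_warning`.
#' @export
fit_theoretical_line <- function(series,
                                 method = c("occupancy", "linear"),
                                 low_region_fraction = 0.25) {
  stopifnot(inherits(series, "dilution_series"))
  method <- match.arg(method)
  keep <- seq_len(detector_valid_prefix(series))
  conc <- series$concentrations[keep]
  y <- series$detected_counts[keep]
  nw <- series$n_windows

  if (method == "occupancy") {
    fit <- suppressWarnings(stats::glm(
      cbind(y, nw - y) ~ 1 + offset(log(conc)),
      family = stats::binomial("cloglog")
    ))
    slope <- nw * exp(unname(stats::coef(fit)[1L]))
    low_max <- max(conc)
    curv <- FALSE
  } else {
    check_number(low_region_fraction, "low_region_fraction",
                 lower = 0, upper = 1, lower_open = TRUE)
    n_low <- floor(low_region_fraction * length(conc))
    if (n_low < 3L) {
      validation_error(sprintf(
        "low region has %d points; at least 3 are required", n_low
      ))
    }
    idx <- seq_len(n_low) # series is sorted by concentration
    slope <- sum(conc[idx] * y[idx]) / sum(conc[idx]^2)
    low_max <- conc[n_low]
    # saturation curvature: a fit on the lower half of the region
    # over-predicts the upper half by more than counting noise
    lower <- idx[idx <= n_low / 2]
    upper <- idx[idx > n_low / 2]
    s_low <- sum(conc[lower] * y[lower]) / sum(conc[lower]^2)
    z <- (y[upper] - s_low * conc[upper]) /
      sqrt(pmax(s_low * conc[upper], 1))
    curv <- is.finite(s_low) && mean(z) < -2
    if (curv) {
      warning(
        "low-region fit shows saturation curvature; the theoretical slope is likely biased low",
        call. = FALSE
      )
    }
  }
  if (!is.finite(slope) || slope <= 0) {
    spicpms_error("theoretical slope is not positive",
                  "spicpms_calibration_error")
  }
  structure(
    list(slope = slope, method = method, low_region_max_conc = low_max,
         curvature_warning = curv),
    class = "theoretical_line"
  )
}

#' Critical detected-particle count of a dilution series
#'
#' Operationalizes the difference-curve reading of counting linearity:
#' for each sample the relative shortfall is
#' `(theoretical - detected) / theoretical`. Scanning samples in
#' increasing concentration order, the linear region ends at the first
#' sustained breach: `sustain` consecutive samples whose shortfall exceeds
#' `tolerance` *and* whose absolute difference exceeds `min_z` counting
#' standard errors (`min_z * sqrt(theoretical)`), the latter so that the
#' Poisson noise of low-count samples cannot fake a breach. The critical
#' count is the largest detected count among in-tolerance samples up to
#' the breach, refined by linear interpolation of the shortfall between
#' the last in-tolerance sample and the first breaching one (the ladder
#' grid is coarse near the breakpoint).
#'
#' Samples past a detector-overload collapse (a drop of the detected count
#' by more than 3 counting standard errors below its running maximum; see
#' the package vignette) are excluded from the scan and counted in
#' `n_excluded`; the same exclusion applies inside
#' [fit_theoretical_line()].
#'
#' With 3000 windows the default tolerance 0.085 places the critical count
#' near 500 detected particles per acquisition: the Poisson-occupancy
#' shortfall `1 - (1 - exp(-lambda)) / lambda` reaches 0.085 at
#' `lambda ~ 0.18` particles per window.
#'
#' @param series A [dilution_series()].
#' @param slope Theoretical slope, counts per (pg/mL): a number or a
#'   `theoretical_line`.
#' @param tolerance Relative-shortfall tolerance, in (0, 0.5). Default
#'   0.085.
#' @param min_z Counting-noise guard on breaches, in standard errors.
#'   Default 3; 0 disables the guard.
#' @param sustain Number of consecutive breaching samples required.
#'   Default 2.
#'
#' @return An object of class `linearity_result`: the sorted
#'   `concentrations` and `detected_counts`, `theoretical` counts,
#'   `differences` (theoretical - detected), `shortfall`,
#'   `theoretical_slope`, `tolerance`, `critical_count` (integer),
#'   `saturation_observed` (FALSE when no sample breaches, in which case
#'   the critical count is the maximum detected count), and `n_windows`.
#' @export
critical_count <- function(series, slope, tolerance = 0.085,
                           min_z = 3, sustain = 2) {
  stopifnot(inherits(series, "dilution_series"))
  if (inherits(slope, "theoretical_line")) slope <- slope$slope
  check_number(slope, "slope", lower = 0, lower_open = TRUE)
  check_number(tolerance, "tolerance", lower = 0, upper = 0.5,
               lower_open = TRUE, upper_open = TRUE)
  check_number(min_z, "min_z", lower = 0)
  check_number(sustain, "sustain", lower = 1, integer = TRUE)

  keep <- seq_len(detector_valid_prefix(series))
  n_excluded <- length(series$concentrations) - length(keep)
  conc <- series$concentrations[keep]
  y <- series$detected_counts[keep]
  theo <- slope * conc
  diff <- theo - y
  shortfall <- diff / theo

  breach <- shortfall > tolerance
  if (min_z > 0) breach <- breach & diff > min_z * sqrt(theo)

  # first run of `sustain` consecutive breaches
  first_breach <- NA_integer_
  if (any(breach)) {
    run <- stats::filter(as.numeric(breach), rep(1, sustain), sides = 1)
    hit <- which(!is.na(run) & run == sustain)
    if (length(hit)) first_breach <- hit[1L] - sustain + 1L
  }

  if (is.na(first_breach)) {
    crit <- max(y)
    saturated <- FALSE
  } else {
    saturated <- TRUE
    scan <- seq_len(first_breach)
    ok <- scan[shortfall[scan] <= tolerance]
    if (!length(ok)) {
      spicpms_error(
        "no sample is within the linearity tolerance: no linear region",
        "spicpms_no_linear_region_error"
      )
    }
    j <- max(ok)
    crit <- max(y[ok])
    # interpolate the tolerance crossing against the first sample whose
    # shortfall exceeds it (the scan-stopping breach may lie further out)
    over <- scan[scan > j & shortfall[scan] > tolerance]
    if (length(over)) {
      i <- over[1L]
      if (shortfall[i] > shortfall[j]) {
        frac <- (tolerance - shortfall[j]) / (shortfall[i] - shortfall[j])
        crit <- max(crit, y[j] + frac * (y[i] - y[j]))
      }
    }
  }

  structure(
    list(
      concentrations = conc,
      detected_counts = y,
      theoretical = theo,
      differences = diff,
      shortfall = shortfall,
      theoretical_slope = slope,
      tolerance = tolerance,
      min_z = min_z,
      sustain = sustain,
      critical_count = as.integer(round(crit)),
      saturation_observed = saturated,
      n_excluded = n_excluded,
      n_windows = series$n_windows
    ),
    class = "linearity_result"
  )
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf(
    paste0("<linearity_result> %d samples, slope %.4g counts/(pg/mL)\n",
           "  critical count %d (tolerance %.3g)%s\n"),
    length(x$concentrations), x$theoretical_slope, x$critical_count,
    x$tolerance,
    if (x$saturation_observed) "" else " [no saturation observed]"
  ))
  invisible(x)
}
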