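# Calibration: ionic sensitivity from a standard ladder, and transport
# efficiency from a particle reference standard of known number
# concentration (the particle-frequency method).

#' Fit the ionic calibration line
#'
#' Ordinary least squares of mean per-dwell intensity on dissolved standard
#' concentration. The slope is the ionic sensitivity used for event-mass
#' conversion and for reading the dissolved concentration off the
#' background.
#'
#' @param standards A data frame (or list coercible to one) with columns
#'   `concentration` (ng/mL) and `mean_intensity` (counts per dwell); at
#'   least two distinct concentrations.
#'
#' @return An object of class `ionic_calibration` with `slope`
#'   (counts/dwell per ng/mL), `intercept` (counts/dwell), and `r_squared`.
#' @export
#' @examples
#' fit_ionic_calibration(data.frame(
#'   concentration = c(0, 1, 2), mean_intensity = c(0, 10, 20)
#' ))
fit_ionic_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration", "mean_intensity") %in% names(standards))) {
    validation_error(
      "`standards` needs columns `concentration` and `mean_intensity`"
    )
  }
  conc <- standards$concentration
  y <- standards$mean_intensity
  check_numeric_vector(conc, "concentration", min_length = 2L)
  check_numeric_vector(y, "mean_intensity", min_length = 2L)
  if (length(conc) != length(y)) {
    validation_error("`concentration` and `mean_intensity` differ in length")
  }
  if (length(unique(conc)) < 2L) {
    validation_error("at least two distinct concentrations are required")
  }

  fit <- stats::lm(y ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  flat <- abs(slope) * diff(range(conc)) <=
    1e-8 * (mean(abs(y)) + 1) # no resolvable response over the ladder
  if (!is.finite(slope) || slope <= 0 || flat) {
    spicpms_error(
      sprintf("non-positive calibration slope (%.3g): flat or inverted response",
              slope),
      "spicpms_calibration_error"
    )
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2),
    class = "ionic_calibration"
  )
}

#' Transport efficiency by the particle-frequency method
#'
#' From a measurement of a reference particle standard of known number
#' concentration: the transport efficiency is the ratio of detected events
#' to the number of particles delivered to the nebulizer,
#' `eta = n_events / (reference_number_conc * sample_flow * duration)`.
#'
#' @param detection A `detection_result` for the reference standard.
#' @param reference_number_conc Known number concentration of the
#'   reference, particles/mL.
#' @param sample_flow Sample uptake, mL/s.
#' @param duration Acquisition time, s.
#' @param critical_count Optional coincidence guard: warn when the
#'   reference measurement itself exceeds this detected-event count (see
#'   [critical_count()]), since coincidence in the reference biases eta
#'   low.
#'
#' @return An object of class `transport_efficiency` with `eta`, `method`
#'   (`"particle-frequency"`), and `reference_number_conc`.
#' @export
transport_efficiency_particle_frequency <- function(detection,
                                                    reference_number_conc,
                                                    sample_flow,
                                                    duration,
                                                    critical_count = NULL) {
  stopifnot(inherits(detection, "detection_result"))
  check_number(reference_number_conc, "reference_number_conc",
               lower = 0, lower_open = TRUE)
  check_number(sample_flow, "sample_flow", lower = 0, lower_open = TRUE)
  check_number(duration, "duration", lower = 0, lower_open = TRUE)

  n <- detection$n_events
  if (n < 1L) {
    spicpms_error("no events detected in the reference measurement",
                  "spicpms_insufficient_signal_error")
  }
  if (!is.null(critical_count) && n > critical_count) {
    warning(sprintf(
      "reference measurement has %d events, above the critical count %d; coincidence will bias eta low",
      n, as.integer(critical_count)
    ), call. = FALSE)
  }
  eta <- n / (reference_number_conc * sample_flow * duration)
  if (eta > 1) {
    spicpms_error(
      sprintf("eta = %.3g > 1: detected events exceed delivered particles",
              eta),
      "spicpms_inconsistent_reference_error"
    )
  }
  structure(
    list(eta = eta, method = "particle-frequency",
         reference_number_conc = reference_number_conc),
    class = "transport_efficiency"
  )
}

#' Wrap a known transport efficiency
#'
#' For workflows where the transport efficiency is known (e.g. simulation
#' ground truth) rather than measured.
#'
#' @param eta Transport efficiency in (0, 1].
#' @return An object of class `transport_efficiency`.
#' @export
transport_efficiency <- function(eta) {
  check_number(eta, "eta", lower = 0, upper = 1, lower_open = TRUE)
  structure(
    list(eta = eta, method = "known", reference_number_conc = NA_real_),
    class = "transport_efficiency"
  )
}
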