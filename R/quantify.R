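# Event-to-particle conversion and per-sample quantification: net event
# intensity -> analyte mass -> spherical-equivalent diameter, plus number,
# particulate-mass and dissolved concentrations.

#' Convert net event intensity to analyte mass
#'
#' A dissolved concentration C produces `calib$slope * C` counts per dwell,
#' and the analyte mass flowing through the plasma per dwell window at
#' concentration C is `C * transport_efficiency * sample_flow * dwell_time`.
#' Equating the two mass fluxes, a particle event of net intensity I
#' carries
#' `mass = I * (eta * sample_flow * dwell_time) / calib$slope` (ng,
#' returned in fg).
#'
#' @param net_intensity Net event intensity (raw minus background mean),
#'   counts per dwell; vectorized.
#' @param calib An `ionic_calibration` (only the slope is used).
#' @param eta A `transport_efficiency`.
#' @param sample_flow Sample uptake, mL/s.
#' @param dwell_time Dwell time, s.
#'
#' @return Analyte mass per event, fg.
#' @export
#' @examples
#' cal <- fit_ionic_calibration(data.frame(
#'   concentration = 0:2, mean_intensity = c(0, 10, 20)
#' ))
#' event_mass(100, cal, transport_efficiency(0.1),
#'            sample_flow = 5e-3, dwell_time = 0.01) # 50 fg
event_mass <- function(net_intensity, calib, eta, sample_flow, dwell_time) {
  stopifnot(inherits(calib, "ionic_calibration"),
            inherits(eta, "transport_efficiency"))
  check_numeric_vector(net_intensity, "net_intensity")
  if (any(net_intensity <= 0)) {
    validation_error("`net_intensity` must be strictly positive")
  }
  check_number(sample_flow, "sample_flow", lower = 0, lower_open = TRUE)
  check_number(dwell_time, "dwell_time", lower = 0, lower_open = TRUE)
  mass_ng <- net_intensity * (eta$eta * sample_flow * dwell_time) /
    calib$slope
  mass_ng * 1e6 # fg
}

#' Spherical-equivalent diameter from analyte mass
#'
#' Inverse of the sphere-mass formula
#' `mass = (pi/6) * density * d^3 * mass_fraction`:
#' `d = (6 * mass / (pi * density * mass_fraction))^(1/3)`.
#'
#' @param mass Analyte mass, fg; vectorized, `>= 0`.
#' @param element An [element_properties()] object; default [silver()].
#' @return Diameter, nm.
#' @export
#' @examples
#' mass_to_diameter(5.4926, silver()) # ~100 nm
mass_to_diameter <- function(mass, element = silver()) {
  stopifnot(inherits(element, "element_properties"))
  if (!is.numeric(mass) || anyNA(mass) || any(!is.finite(mass)) ||
      any(mass < 0)) {
    validation_error("`mass` must be finite and non-negative")
  }
  (6 * mass * 1e6 / (pi * element$density * element$mass_fraction))^(1 / 3)
}

#' Analyte mass of a sphere of given diameter
#'
#' @param diameter Diameter, nm; vectorized.
#' @param element An [element_properties()] object; default [silver()].
#' @return Analyte mass, fg.
#' @export
diameter_to_mass <- function(diameter, element = silver()) {
  stopifnot(inherits(element, "element_properties"))
  if (!is.numeric(diameter) || anyNA(diameter) || any(diameter < 0)) {
    validation_error("`diameter` must be finite and non-negative")
  }
  sphere_mass_fg(diameter, element$density, element$mass_fraction)
}

#' Quantify a sample from its detection result
#'
#' Converts detected events to per-sample summary quantities:
#' \describe{
#'   \item{number_concentration}{`n_events / (eta * sample_flow * duration)`,
#'     particles/mL.}
#'   \item{particulate_mass_concentration}{Sum of event analyte masses over
#'     the analyzed volume, ng/mL.}
#'   \item{dissolved_concentration}{`(background_mean - calib$intercept) /
#'     calib$slope`, clipped at 0 (a negative raw value is reported via a
#'     message), ng/mL.}
#'   \item{size_lod}{Diameter corresponding to the smallest detectable net
#'     intensity, `max(threshold - background_mean, 1)` counts, nm.}
#' }
#' Net event intensity is raw minus the background mean (not minus the
#' threshold), which keeps event masses unbiased at the cost of a soft
#' size floor; the floor is reported as `size_lod`.
#'
#' @param detection A `detection_result`.
#' @param calib An `ionic_calibration`.
#' @param eta A `transport_efficiency`.
#' @param settings An [acquisition_settings()] object.
#' @param element An [element_properties()] object; default [silver()].
#'
#' @return An object of class `quant_result` with the summary fields,
#'   diameter statistics (`mean_diameter`, `median_diameter`,
#'   `sd_diameter`, `NA` when no events), the event table `events`
#'   (window_index, raw, net, mass_fg, diameter_nm), and `diameters`.
#' @export
quantify_sample <- function(detection, calib, eta, settings,
                            element = silver()) {
  stopifnot(inherits(detection, "detection_result"),
            inherits(calib, "ionic_calibration"),
            inherits(eta, "transport_efficiency"),
            inherits(settings, "acquisition_settings"),
            inherits(element, "element_properties"))

  flow <- settings$sample_flow
  analyzed_volume <- eta$eta * flow * settings$duration # mL

  n <- detection$n_events
  if (n > 0L) {
    net <- detection$event_raw_intensities - detection$background_mean
    mass <- event_mass(net, calib, eta, flow, settings$dwell_time)
    diam <- mass_to_diameter(mass, element)
  } else {
    net <- numeric(0)
    mass <- numeric(0)
    diam <- numeric(0)
  }

  raw_dissolved <- (detection$background_mean - calib$intercept) /
    calib$slope
  if (raw_dissolved < -1e-9) {
    message(sprintf(
      "background below calibration intercept: raw dissolved concentration %.3g ng/mL clipped to 0",
      raw_dissolved
    ))
  }

  lod_net <- max(detection$threshold - detection$background_mean, 1)
  size_lod <- mass_to_diameter(
    event_mass(lod_net, calib, eta, flow, settings$dwell_time), element
  )

  structure(
    list(
      n_events = n,
      number_concentration = n / analyzed_volume,
      particulate_mass_concentration = sum(mass) * 1e-6 / analyzed_volume,
      # below 1e-12 ng/mL is numerical dust from the calibration intercept
      dissolved_concentration = if (raw_dissolved < 1e-12) 0
                                else raw_dissolved,
      mean_diameter = if (n > 0L) mean(diam) else NA_real_,
      median_diameter = if (n > 0L) stats::median(diam) else NA_real_,
      sd_diameter = if (n > 1L) stats::sd(diam) else NA_real_,
      size_lod = size_lod,
      diameters = diam,
      events = data.frame(
        window_index = detection$event_indices,
        raw = detection$event_raw_intensities,
        net = net,
        mass_fg = mass,
        diameter_nm = diam
      ),
      settings = settings
    ),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    paste0("<quant_result> %d events\n",
           "  number conc.      %.4g particles/mL\n",
           "  particulate mass  %.4g ng/mL\n",
           "  dissolved         %.4g ng/mL\n",
           "  diameter          %.4g nm (median %.4g, sd %.3g), LOD %.3g nm\n"),
    x$n_events, x$number_concentration, x$particulate_mass_concentration,
    x$dissolved_concentration, x$mean_diameter, x$median_diameter,
    x$sd_diameter, x$size_lod
  ))
  invisible(x)
}
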