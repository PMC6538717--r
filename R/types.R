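#' Acquisition settings for an sp-ICP-MS run
#'
#' Bundles the instrument parameters every stage of the pipeline needs:
#' dwell time, total acquisition time, sample uptake flow, transport
#' efficiency, and the ionic calibration (sensitivity) that links dissolved
#' analyte concentration to per-dwell counts.
#'
#' All intensities in the package are expressed as counts per dwell window,
#' never counts per second, so the dwell time enters the bookkeeping in
#' exactly one place. The canonical internal units are seconds, mL, ng, nm
#' and fg; ng/mL and ug/L are the same unit.
#'
#' @param dwell_time Dwell (integration) time of one reading, seconds.
#'   Default 0.010 s.
#' @param duration Total acquisition time, seconds. Default 30 s, giving
#'   3000 dwell windows at the default dwell time.
#' @param sample_flow Sample uptake rate, mL per second. Default
#'   0.346/60 (0.346 mL/min, an illustrative typical nebulizer uptake).
#' @param transport_efficiency Fraction of nebulized sample reaching the
#'   plasma, in (0, 1]. Default 0.05. Together with `sample_flow` it sets
#'   the particle arrival rate; only the product matters for most results.
#' @param calib_slope Ionic sensitivity, counts per dwell per (ng/mL).
#'   Default 500 (50,000 cps per ng/mL at 10 ms dwell, a typical silver
#'   sensitivity).
#' @param calib_intercept Instrument background, counts per dwell.
#'   Default 0.
#'
#' @return An object of class `acquisition_settings`.
#' @seealso [simulate_trace()], [quantify_sample()]
#' @export
#' @examples
#' s <- acquisition_settings()
#' n_windows(s) # 3000
acquisition_settings <- function(dwell_time = 0.010,
                                 duration = 30,
                                 sample_flow = 0.346 / 60,
                                 transport_efficiency = 0.05,
                                 calib_slope = 500,
                                 calib_intercept = 0) {
  check_number(dwell_time, "dwell_time", lower = 0, lower_open = TRUE)
  check_number(duration, "duration", lower = dwell_time)
  check_number(sample_flow, "sample_flow", lower = 0, lower_open = TRUE)
  check_number(transport_efficiency, "transport_efficiency",
               lower = 0, upper = 1, lower_open = TRUE)
  check_number(calib_slope, "calib_slope", lower = 0, lower_open = TRUE)
  check_number(calib_intercept, "calib_intercept", lower = 0)
  if (floor(duration / dwell_time) < 1) {
    validation_error("`duration` must cover at least one dwell window")
  }
  structure(
    list(
      dwell_time = dwell_time,
      duration = duration,
      sample_flow = sample_flow,
      transport_efficiency = transport_efficiency,
      calib_slope = calib_slope,
      calib_intercept = calib_intercept
    ),
    class = "acquisition_settings"
  )
}

#' Number of dwell windows in an acquisition
#'
#' @param settings An [acquisition_settings()] object.
#' @return Integer number of dwell windows, `floor(duration / dwell_time)`.
#' @export
n_windows <- function(settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  as.integer(floor(settings$duration / settings$dwell_time))
}

#' Nanoparticle population description
#'
#' Ground-truth description of a monodisperse-to-narrow nanoparticle stock:
#' lognormal diameter distribution, number concentration, and the material
#' properties needed to convert diameters to analyte mass.
#'
#' @param mean_diameter Arithmetic mean particle diameter, nm.
#' @param number_concentration Particles per mL.
#' @param cv_diameter Coefficient of variation of the lognormal diameter
#'   distribution. Default 0.05, appropriate for narrowly distributed
#'   commercial stocks.
#' @param density Particle material density, g/cm^3. Default 10.49
#'   (metallic silver).
#' @param mass_fraction Analyte mass fraction of the particle, in (0, 1].
#'   Default 1 (pure-element particles).
#'
#' @return An object of class `particle_population`.
#' @export
#' @examples
#' nag100 <- particle_population(100, number_concentration = 3.5e4)
particle_population <- function(mean_diameter,
                                number_concentration,
                                cv_diameter = 0.05,
                                density = 10.49,
                                mass_fraction = 1) {
  check_number(mean_diameter, "mean_diameter", lower = 0, lower_open = TRUE)
  check_number(cv_diameter, "cv_diameter", lower = 0)
  check_number(number_concentration, "number_concentration", lower = 0)
  check_number(density, "density", lower = 0, lower_open = TRUE)
  check_number(mass_fraction, "mass_fraction", lower = 0, upper = 1,
               lower_open = TRUE)
  structure(
    list(
      mean_diameter = mean_diameter,
      cv_diameter = cv_diameter,
      number_concentration = number_concentration,
      density = density,
      mass_fraction = mass_fraction
    ),
    class = "particle_population"
  )
}

#' Element properties for mass/diameter conversion
#'
#' @param symbol Element label.
#' @param density Particle material density, g/cm^3.
#' @param mass_fraction Analyte mass fraction of the particle, in (0, 1].
#' @return An object of class `element_properties`.
#' @export
#' @examples
#' silver() # the package default
element_properties <- function(symbol, density, mass_fraction = 1) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  check_number(density, "density", lower = 0, lower_open = TRUE)
  check_number(mass_fraction, "mass_fraction", lower = 0, upper = 1,
               lower_open = TRUE)
  structure(
    list(symbol = symbol, density = density, mass_fraction = mass_fraction),
    class = "element_properties"
  )
}

#' @rdname element_properties
#' @export
silver <- function() element_properties("Ag", density = 10.49)

#' Pretreatment / matrix scenario transform
#'
#' Phenomenological description of what a pretreatment (or the in-vivo
#' environment) does to a nanoparticle suspension before measurement:
#' a fraction of the particulate mass is ionized into the dissolved pool,
#' a fraction of the remaining particles aggregates into k-mers, and the
#' sample is diluted for measurement.
#'
#' @param ionized_fraction Fraction of particulate analyte mass moved into
#'   the dissolved pool, in \[0, 1\]. Acidic digests correspond to values
#'   near 1, alkaline digests to 0.
#' @param aggregated_fraction Fraction of the (post-ionization) particles
#'   that merge into aggregates, in \[0, 1\].
#' @param aggregate_order Number of monomers per aggregate, integer >= 2.
#'   A k-mer has diameter `d * k^(1/3)` (mass conservation).
#' @param dilution_factor Measurement dilution applied to every
#'   concentration, >= 1.
#'
#' @return An object of class `scenario_transform`.
#' @seealso [apply_scenario()]
#' @export
scenario_transform <- function(ionized_fraction = 0,
                               aggregated_fraction = 0,
                               aggregate_order = 2,
                               dilution_factor = 1) {
  check_number(ionized_fraction, "ionized_fraction", lower = 0, upper = 1)
  check_number(aggregated_fraction, "aggregated_fraction",
               lower = 0, upper = 1)
  check_number(aggregate_order, "aggregate_order", lower = 2, integer = TRUE)
  check_number(dilution_factor, "dilution_factor", lower = 1)
  if (ionized_fraction + aggregated_fraction > 1) {
    validation_error(
      "ionized_fraction + aggregated_fraction must not exceed 1"
    )
  }
  structure(
    list(
      ionized_fraction = ionized_fraction,
      aggregated_fraction = aggregated_fraction,
      aggregate_order = aggregate_order,
      dilution_factor = dilution_factor
    ),
    class = "scenario_transform"
  )
}

#' Detection parameters for iterative mean + k-sigma thresholding
#'
#' @param k_sigma Threshold multiplier: a window is above threshold when
#'   its intensity strictly exceeds `mean + k_sigma * sd` of the current
#'   background set. Default 3; use 5 for very low backgrounds where the
#'   Poisson tail of the background would otherwise leak into the events.
#' @param max_iterations Maximum number of background-refinement passes.
#' @param min_background_windows Minimum number of windows that must remain
#'   classified as background; fewer is treated as a degenerate trace.
#' @return An object of class `detection_params`.
#' @seealso [detect_events()]
#' @export
detection_params <- function(k_sigma = 3,
                             max_iterations = 100,
                             min_background_windows = 10) {
  check_number(k_sigma, "k_sigma", lower = 0, lower_open = TRUE)
  check_number(max_iterations, "max_iterations", lower = 1, integer = TRUE)
  check_number(min_background_windows, "min_background_windows",
               lower = 2, integer = TRUE)
  structure(
    list(
      k_sigma = k_sigma,
      max_iterations = max_iterations,
      min_background_windows = min_background_windows
    ),
    class = "detection_params"
  )
}

#' Sample preparation description for spike-recovery bookkeeping
#'
#' @param spike_concentration Known analyte spike at the homogenate level,
#'   ng/mL.
#' @param measurement_dilution Dilution between homogenate and measured
#'   solution, >= 1.
#' @param tissue_mass Initial tissue mass, g.
#' @param homogenate_ratio Buffer volume per tissue mass (w/v).
#' @param reagent_ratio Solubilizer volume per homogenate volume (v/v).
#' @return An object of class `sample_prep`.
#' @seealso [recovery_rates()]
#' @export
sample_prep <- function(spike_concentration = 100,
                        measurement_dilution = 500,
                        tissue_mass = 1,
                        homogenate_ratio = 10,
                        reagent_ratio = 1) {
  check_number(spike_concentration, "spike_concentration",
               lower = 0, lower_open = TRUE)
  check_number(measurement_dilution, "measurement_dilution", lower = 1)
  check_number(tissue_mass, "tissue_mass", lower = 0, lower_open = TRUE)
  check_number(homogenate_ratio, "homogenate_ratio",
               lower = 0, lower_open = TRUE)
  check_number(reagent_ratio, "reagent_ratio", lower = 0, lower_open = TRUE)
  structure(
    list(
      spike_concentration = spike_concentration,
      measurement_dilution = measurement_dilution,
      tissue_mass = tissue_mass,
      homogenate_ratio = homogenate_ratio,
      reagent_ratio = reagent_ratio
    ),
    class = "sample_prep"
  )
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat(sprintf(
    paste0("<acquisition_settings> dwell %g s, duration %g s (%d windows),\n",
           "  flow %g mL/s, transport efficiency %g,\n",
           "  sensitivity %g counts/dwell/(ng/mL), background %g counts/dwell\n"),
    x$dwell_time, x$duration, n_windows(x), x$sample_flow,
    x$transport_efficiency, x$calib_slope, x$calib_intercept
  ))
  invisible(x)
}

#' @export
print.particle_population <- function(x, ...) {
  cat(sprintf(
    "<particle_population> %g nm (CV %g), %g particles/mL, density %g g/cm^3\n",
    x$mean_diameter, x$cv_diameter, x$number_concentration, x$density
  ))
  invisible(x)
}
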