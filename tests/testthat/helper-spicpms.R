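# Shared fixtures: the reference acquisition (10 ms dwell, 30 s, 3000
# windows) and an exactly known ionic calibration.

ref_settings <- function(calib_slope = 500, calib_intercept = 0, ...) {
  acquisition_settings(calib_slope = calib_slope,
                       calib_intercept = calib_intercept, ...)
}

# calibration whose slope/intercept are recovered exactly from a noiseless
# standard ladder
known_calibration <- function(slope = 500, intercept = 0) {
  conc <- c(0, 1, 2, 5, 10)
  fit_ionic_calibration(data.frame(
    concentration = conc,
    mean_intensity = intercept + slope * conc
  ))
}

# analyte mass (fg) of a silver sphere, independent of the package's
# conversion chain
ag_sphere_mass_fg <- function(d_nm) pi / 6 * 10.49 * d_nm^3 * 1e-6

# volume of sample reaching the plasma over one acquisition, mL
analyzed_volume <- function(settings) {
  settings$transport_efficiency * settings$sample_flow * settings$duration
}

# population dialed to a target expected number of particle arrivals
population_for_events <- function(n_events, settings, mean_diameter = 100,
                                  cv = 0.05) {
  particle_population(
    mean_diameter,
    number_concentration = number_conc_for_events(n_events, settings),
    cv_diameter = cv
  )
}

# the ladder of the counting-linearity experiment
ladder_start_concs <- c(2000, 800, 700, 600)

simulate_ladder <- function(settings, seed, cv = 0.05) {
  stock <- particle_population(100, number_concentration = 0,
                               cv_diameter = cv)
  simulate_dilution_series(stock, ladder_start_concs, n_steps = 10,
                           step_factor = 2, settings = settings, seed = seed)
}
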