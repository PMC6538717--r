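# Event mass, spherical-equivalent diameter, per-sample quantification.

test_that("event mass follows the dissolved mass-flux equivalence", {
  cal <- fit_ionic_calibration(data.frame(
    concentration = c(0, 1, 2), mean_intensity = c(0, 10, 20)
  ))
  # hand unit chain: 100 counts x (0.1 x 5e-3 mL/s x 0.01 s) / 10 counts
  # per dwell per (ng/mL) = 5e-5 ng = 50 fg
  m <- event_mass(100, cal, transport_efficiency(0.1),
                  sample_flow = 5e-3, dwell_time = 0.01)
  expect_equal(m, 50)

  # proportionality in eta and in intensity
  expect_equal(
    event_mass(100, cal, transport_efficiency(0.2), 5e-3, 0.01), 2 * m
  )
  expect_equal(
    event_mass(c(50, 100), cal, transport_efficiency(0.1), 5e-3, 0.01),
    c(m / 2, m)
  )
  expect_error(event_mass(0, cal, transport_efficiency(0.1), 5e-3, 0.01),
               class = "spicpms_validation_error")
})

test_that("mass and diameter invert the sphere-mass formula", {
  expect_equal(mass_to_diameter(0), 0)
  # (pi/6) x 10.49 g/cm^3 x (100 nm)^3 = 5.4926 fg
  expect_equal(mass_to_diameter(ag_sphere_mass_fg(100)), 100,
               tolerance = 1e-12)
  expect_equal(mass_to_diameter(ag_sphere_mass_fg(30)), 30,
               tolerance = 1e-12)
  expect_equal(ag_sphere_mass_fg(100), 5.494, tolerance = 1e-3)
  expect_equal(ag_sphere_mass_fg(30), 0.1483, tolerance = 1e-3)

  # round trip at 1e-12 relative tolerance across the working range
  d <- exp(seq(log(1), log(1000), length.out = 50))
  expect_equal(mass_to_diameter(diameter_to_mass(d)), d, tolerance = 1e-12)

  # mass_fraction enters both directions consistently
  half <- element_properties("X", density = 10.49, mass_fraction = 0.5)
  expect_equal(mass_to_diameter(diameter_to_mass(d, half), half), d,
               tolerance = 1e-12)
  expect_error(mass_to_diameter(-1), class = "spicpms_validation_error")
})

test_that("quantification of a background-only trace gives the dissolved split", {
  s <- ref_settings(calib_slope = 10)
  det <- detect_events(rep(50, 200))
  q <- quantify_sample(det, known_calibration(10), transport_efficiency(0.05),
                       s)
  expect_identical(q$n_events, 0L)
  expect_equal(q$number_concentration, 0)
  expect_equal(q$dissolved_concentration, 5)
  expect_true(is.na(q$mean_diameter))
  expect_identical(nrow(q$events), 0L)
})

test_that("number concentration is events over analyzed volume", {
  # 500 events, eta 0.05, flow 5.767e-3 mL/s, 30 s
  s <- acquisition_settings(sample_flow = 5.767e-3, calib_slope = 500)
  # 500 events occupy 1/6 of the windows: their standardized deviation,
  # (1-f)/sqrt(f(1-f)) = 2.24, needs k below it to be shed
  x <- rep(0L, 3000); x[seq_len(500) * 6] <- 400L
  q <- quantify_sample(detect_events(x, detection_params(k_sigma = 2)),
                       known_calibration(), transport_efficiency(0.05), s)
  expect_identical(q$n_events, 500L)
  expect_equal(q$number_concentration, 500 / (0.05 * 5.767e-3 * 30))
  expect_equal(q$number_concentration, 5.78e4, tolerance = 1e-3)
})

test_that("the full pipeline recovers the simulated diameter", {
  s <- ref_settings()
  pop <- population_for_events(200, s)
  q <- quantify_sample(
    detect_events(simulate_trace(pop, 0, s, seed = 21)),
    known_calibration(), transport_efficiency(0.05), s
  )
  expect_equal(q$mean_diameter, 100, tolerance = 0.03)
  expect_equal(q$sd_diameter, 5, tolerance = 0.5) # CV 5% population
})

test_that("particulate plus dissolved mass balances the simulated total", {
  s <- ref_settings()
  pop <- population_for_events(300, s)
  true_part <- particulate_mass_conc(pop)
  true_diss <- 0.1
  totals <- vapply(1:10, function(seed) {
    tr <- simulate_trace(pop, true_diss, s, seed = 300 + seed)
    q <- quantify_sample(detect_events(tr), known_calibration(),
                         transport_efficiency(0.05), s)
    q$particulate_mass_concentration + q$dissolved_concentration
  }, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - (true_part + true_diss)), 3 * se)
})

test_that("above the critical count the mean diameter is overestimated", {
  s <- ref_settings()
  pop <- population_for_events(1500, s) # lambda = 0.5, far above critical
  for (seed in 1:5) {
    q <- quantify_sample(
      detect_events(simulate_trace(pop, 0, s, seed = 400 + seed)),
      known_calibration(), transport_efficiency(0.05), s
    )
    expect_gt(q$mean_diameter, 100)
  }
})

test_that("recovered concentrations scale back up through a dilution", {
  s <- ref_settings()
  pop <- population_for_events(300, s)
  target <- particulate_mass_conc(pop)
  f <- 10
  diluted <- particle_population(100,
    number_concentration = pop$number_concentration / f)
  recovered <- vapply(1:10, function(seed) {
    q <- quantify_sample(
      detect_events(simulate_trace(diluted, 0, s, seed = 500 + seed)),
      known_calibration(), transport_efficiency(0.05), s
    )
    q$particulate_mass_concentration * f
  }, numeric(1))
  se <- sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - target), 3 * se)
})

test_that("size LOD reports the soft floor set by the threshold", {
  s <- ref_settings(calib_intercept = 5)
  tr <- simulate_trace(population_for_events(100, s), 0, s, seed = 31)
  det <- detect_events(tr, detection_params(k_sigma = 5))
  q <- quantify_sample(det, known_calibration(), transport_efficiency(0.05), s)
  lod_net <- det$threshold - det$background_mean
  expect_equal(
    q$size_lod,
    mass_to_diameter(event_mass(lod_net, known_calibration(),
                                transport_efficiency(0.05),
                                s$sample_flow, s$dwell_time))
  )
  expect_gt(q$size_lod, 0)
})
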