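# Simulator: trace layout, seed determinism, Poisson arrival/occupancy
# statistics, scenario transforms, dilution ladders.

test_that("trace has one window per dwell and is empty when nothing is simulated", {
  s <- ref_settings()
  pop <- particle_population(100, number_concentration = 0)
  tr <- simulate_trace(pop, dissolved_conc = 0, settings = s, seed = 1)
  expect_length(tr$intensities, 3000L)
  expect_true(all(tr$intensities == 0L))
  expect_identical(tr$truth$n_particles, 0L)

  # window count is floor(duration / dwell)
  s2 <- ref_settings(duration = 29.995)
  expect_identical(n_windows(s2), 2999L)
})

test_that("identical seed gives bit-identical traces, different seeds differ", {
  s <- ref_settings()
  pop <- population_for_events(300, s)
  a <- simulate_trace(pop, 0.1, s, seed = 42)
  b <- simulate_trace(pop, 0.1, s, seed = 42)
  c <- simulate_trace(pop, 0.1, s, seed = 43)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))

  # the caller's RNG stream is left untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_trace(pop, 0, s, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("occupied-window counts match the Poisson occupancy closed form", {
  s <- ref_settings()
  nw <- 3000
  # 547 expected arrivals -> expected occupied windows 3000 (1 - e^(-547/3000))
  pop <- population_for_events(547, s)
  occ <- vapply(1:200, function(seed) {
    simulate_trace(pop, 0, s, seed = seed)$truth$n_occupied_windows
  }, numeric(1))
  expected <- nw * (1 - exp(-547 / nw))
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - expected), 3 * se)
  expect_equal(expected, 500.0, tolerance = 1e-3)

  # and across a lambda grid
  for (lambda in c(0.01, 0.1, 0.5, 1)) {
    pop <- population_for_events(lambda * nw, s)
    occ <- vapply(1:40, function(seed) {
      simulate_trace(pop, 0, s, seed = 1000 + seed)$truth$n_occupied_windows
    }, numeric(1))
    expected <- nw * (1 - exp(-lambda))
    se <- max(sd(occ) / sqrt(length(occ)), 1e-6)
    expect_lt(abs(mean(occ) - expected), 3 * se)
  }
})

test_that("arrival counts are linear in concentration at low rates", {
  s <- ref_settings()
  pop <- population_for_events(50, s)
  arrivals <- vapply(1:100, function(seed) {
    simulate_trace(pop, 0, s, seed = seed)$truth$n_particles
  }, numeric(1))
  se <- sqrt(50 / length(arrivals)) # Poisson
  expect_lt(abs(mean(arrivals) - 50), 3 * se)
})

test_that("background counts follow the calibration line", {
  s <- ref_settings(calib_slope = 10, calib_intercept = 2)
  pop <- particle_population(100, number_concentration = 0)
  tr <- simulate_trace(pop, dissolved_conc = 5, settings = s, seed = 5)
  # mean ~ intercept + slope * conc = 52
  expect_lt(abs(mean(tr$intensities) - 52), 3 * sqrt(52 / 3000))
})

test_that("apply_scenario conserves analyte mass and handles the limits", {
  pop <- particle_population(100, number_concentration = 1e5)
  d0 <- 0.3

  # identity transform changes nothing
  id <- apply_scenario(pop, d0, scenario_transform())
  expect_equal(particulate_mass_conc(id), particulate_mass_conc(pop))
  expect_equal(id$dissolved_conc, d0)

  # full ionization: no particles, all mass dissolved
  acid <- apply_scenario(pop, 0, scenario_transform(ionized_fraction = 1))
  expect_equal(particulate_mass_conc(acid), 0)
  expect_equal(acid$dissolved_conc, particulate_mass_conc(pop))

  # mass conservation across random transforms (before dilution; with
  # dilution the total scales by exactly 1/f)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(1); a <- runif(1, 0, 1 - p)
    k <- sample(2:5, 1); f <- runif(1, 1, 500)
    tf <- scenario_transform(p, a, k, f)
    out <- apply_scenario(pop, d0, tf)
    total_before <- particulate_mass_conc(pop) + d0
    total_after <- particulate_mass_conc(out) + out$dissolved_conc
    expect_equal(total_after * f, total_before, tolerance = 1e-9)
  }
})

test_that("aggregation produces k-mers with cube-root diameters", {
  pop <- particle_population(100, number_concentration = 1e5, cv_diameter = 0)
  out <- apply_scenario(pop, 0, scenario_transform(
    aggregated_fraction = 0.5, aggregate_order = 2
  ))
  d <- vapply(out$populations, `[[`, numeric(1), "mean_diameter")
  n <- vapply(out$populations, `[[`, numeric(1), "number_concentration")
  expect_equal(sort(d), c(100, 100 * 2^(1 / 3)))
  expect_equal(sort(n), c(0.25e5, 0.5e5))
  # number-weighted mean diameter of the mixture
  expect_equal(sum(d * n) / sum(n),
               (0.5 * 100 + 0.25 * 100 * 2^(1 / 3)) / 0.75,
               tolerance = 1e-12)
})

test_that("dilution ladder has the right layout and concentration bookkeeping", {
  s <- ref_settings()
  stock <- particle_population(100, number_concentration = 0, cv_diameter = 0)

  traces <- simulate_dilution_series(stock, ladder_start_concs, n_steps = 10,
                                     step_factor = 2, settings = s, seed = 3)
  expect_length(traces, 40L)
  concs <- vapply(traces, function(tr) tr$truth$mass_conc_pg, numeric(1))
  expect_equal(max(concs), 2000)
  expect_equal(min(concs), 600 / 2^9)

  # n_steps = 1 keeps the start concentrations
  one <- simulate_dilution_series(stock, c(100, 50), n_steps = 1,
                                  settings = s, seed = 3)
  expect_equal(vapply(one, function(tr) tr$truth$mass_conc_pg, numeric(1)),
               c(100, 50))

  # 2000 pg/mL of 100 nm silver -> mass/number conversion via the sphere mass
  nc <- traces[[1L]]$truth$populations[[1L]]$number_concentration
  expect_equal(nc, 2000e-3 / (ag_sphere_mass_fg(100) * 1e-6),
               tolerance = 1e-12)
  expect_equal(nc, 3.64e5, tolerance = 0.01)
})

test_that("invalid simulator inputs are rejected", {
  s <- ref_settings()
  pop <- particle_population(100, number_concentration = 1e5)
  expect_error(simulate_trace(pop, -1, s), class = "spicpms_validation_error")
  expect_error(particle_population(-5, 1e5),
               class = "spicpms_validation_error")
  expect_error(scenario_transform(0.7, 0.5),
               class = "spicpms_validation_error")
  expect_error(
    simulate_trace(
      particle_population(100, number_concentration = 1e12), 0, s
    ),
    class = "spicpms_validation_error"
  )
  expect_error(
    simulate_dilution_series(pop, numeric(0), settings = s),
    class = "spicpms_validation_error"
  )
})
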