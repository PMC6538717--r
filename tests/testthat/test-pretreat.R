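# Pretreatment evaluation: residue, spike recovery, partition, replicate
# summaries, and end-to-end scenario recovery.

quant_stub <- function(particulate, dissolved, mean_d = NA_real_,
                       sd_d = NA_real_) {
  structure(
    list(
      n_events = 0L,
      number_concentration = 0,
      particulate_mass_concentration = particulate,
      dissolved_concentration = dissolved,
      mean_diameter = mean_d,
      sd_diameter = sd_d
    ),
    class = "quant_result"
  )
}

# one pretreated, spiked, diluted sample through the whole chain
run_scenario <- function(transform, seed, spike = 100,
                         settings = ref_settings()) {
  pop <- particle_population(
    100,
    number_concentration = spike / (ag_sphere_mass_fg(100) *
                                      1.0025^3 * 1e-6)
  )
  sample <- apply_scenario(pop, 0, transform)
  tr <- simulate_trace(sample, settings = settings, seed = seed)
  quantify_sample(detect_events(tr), known_calibration(),
                  transport_efficiency(0.05), settings)
}

test_that("residue rate is the undissolved mass percentage", {
  expect_equal(residue_rate(1.0, 0.0), 0)
  expect_equal(residue_rate(1.0, 0.05), 5)  # > 90% dissolved (alkaline)
  expect_equal(residue_rate(1.0, 0.25), 25) # 75% dissolved (acids)
  expect_error(residue_rate(1.0, 1.2), class = "spicpms_validation_error")
  expect_error(residue_rate(0, 0), class = "spicpms_validation_error")
})

test_that("recovery rates back-calculate through the measurement dilution", {
  prep <- sample_prep(spike_concentration = 100, measurement_dilution = 500)
  rep1 <- recovery_rates(quant_stub(0.2, 0), prep)
  expect_equal(rep1$particle_recovery, 100)
  expect_equal(rep1$ion_recovery, 0)
  expect_equal(rep1$total_recovery, 100)
  expect_true(rep1$fda_pass)

  # the 80-120% interval is closed; just outside fails
  expect_false(recovery_rates(quant_stub(0.1598, 0), prep)$fda_pass) # 79.9
  expect_true(recovery_rates(quant_stub(0.16, 0), prep)$fda_pass)   # 80.0
  expect_true(recovery_rates(quant_stub(0.24, 0), prep)$fda_pass)   # 120.0
  expect_false(recovery_rates(quant_stub(0.2402, 0), prep)$fda_pass)
})

test_that("partition fractions close to 100 and reject empty samples", {
  p <- partition(quant_stub(80, 20))
  expect_equal(p$particle_fraction, 80)
  expect_equal(p$ion_fraction, 20)
  expect_equal(p$total_ag, 100)

  expect_equal(partition(quant_stub(0, 5))$ion_fraction, 100)
  expect_error(partition(quant_stub(0, 0)),
               class = "spicpms_undefined_partition_error")

  set.seed(2)
  for (i in 1:20) {
    q <- quant_stub(runif(1, 0, 10), runif(1, 0, 10))
    pr <- partition(q)
    expect_equal(pr$particle_fraction + pr$ion_fraction, 100,
                 tolerance = 1e-9)
  }
})

test_that("the pipeline recovers the configured ionized fraction end-to-end", {
  for (p in c(0, 0.2, 0.5, 0.95)) {
    ions <- vapply(1:3, function(seed) {
      q <- run_scenario(scenario_transform(ionized_fraction = p,
                                           dilution_factor = 500),
                        seed = 700 + seed)
      partition(q)$ion_fraction
    }, numeric(1))
    # binomial-style Monte-Carlo error of the particulate share, driven by
    # the ~312 (1 - p) particle events behind the particulate estimate
    n_events <- max(312 * (1 - p), 1)
    se <- 100 * p * (1 - p) / sqrt(n_events) / sqrt(3)
    expect_lt(abs(mean(ions) - 100 * p), 3 * se + 0.5)
  }
  # complete ionization leaves a purely ionic sample
  q1 <- run_scenario(scenario_transform(ionized_fraction = 1,
                                        dilution_factor = 500), seed = 710)
  expect_equal(partition(q1)$ion_fraction, 100, tolerance = 0.01)
})

test_that("aggregation broadens and raises the detected size distribution", {
  base <- run_scenario(scenario_transform(dilution_factor = 500), seed = 720)
  agg <- run_scenario(
    scenario_transform(aggregated_fraction = 0.3, aggregate_order = 2,
                       dilution_factor = 500),
    seed = 721
  )
  expect_gt(agg$mean_diameter, base$mean_diameter)
  expect_gt(agg$mean_diameter, 102)
  expect_gt(agg$sd_diameter, 1.3 * base$sd_diameter)
})

test_that("recovery percentages are invariant to the measurement dilution", {
  prep_for <- function(f) sample_prep(spike_concentration = 100,
                                      measurement_dilution = f)
  rec <- vapply(c(250, 500), function(f) {
    q <- run_scenario(scenario_transform(dilution_factor = f), seed = 730)
    recovery_rates(q, prep_for(f))$total_recovery
  }, numeric(1))
  expect_equal(rec[1], rec[2], tolerance = 0.15)
  expect_equal(mean(rec), 100, tolerance = 0.10)
})

test_that("compare_reagents summarizes replicates deterministically", {
  prep <- sample_prep(spike_concentration = 100, measurement_dilution = 500)
  r1 <- recovery_rates(quant_stub(0.2, 0, 100, 5), prep, residue = 5)
  r2 <- recovery_rates(quant_stub(0.19, 0.01, 101, 6), prep, residue = 6)
  r3 <- recovery_rates(quant_stub(0.21, 0.005, 99, 4), prep, residue = 4)
  acid <- recovery_rates(quant_stub(0.001, 0.198, NA_real_, NA_real_), prep,
                         residue = 25)

  tab <- compare_reagents(list(
    NaOH = list(r1, r2, r3),
    HNO3 = list(acid, acid, acid),
    PK = list(r1)
  ))
  expect_equal(tab$reagent, c("HNO3", "NaOH", "PK")) # sorted
  expect_equal(tab$n, c(3L, 3L, 1L))
  # identical replicates have zero spread; single replicates have none
  expect_equal(tab$total_recovery_sd[tab$reagent == "HNO3"], 0)
  expect_true(is.na(tab$total_recovery_sd[tab$reagent == "PK"]))
  expect_equal(tab$particle_recovery_mean[tab$reagent == "NaOH"], 100,
               tolerance = 0.01)
  expect_false(tab$fda_pass_all[tab$reagent == "HNO3"] &&
                 tab$total_recovery_mean[tab$reagent == "HNO3"] < 80)

  expect_error(compare_reagents(list()), class = "spicpms_validation_error")
  expect_error(compare_reagents(list(NaOH = list())),
               class = "spicpms_validation_error")
})
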