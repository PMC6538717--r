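#!/usr/bin/env Rscript
# Pretreatment screen: which solubilizing reagent recovers spiked silver
# nanoparticles from a tissue homogenate without changing them?
#
# A liver-like homogenate carrying a 100 ng/mL nAg100 spike is taken
# through five phenomenological reagent scenarios, diluted 500-fold and
# measured by the simulated sp-ICP-MS pipeline (three replicates each):
#   NaOH         identity (particles untouched)
#   TMAH         aggregation (87% of particles into dimers: number-mean
#                diameter moves from 100 to ~120 nm, distribution broadens)
#   HNO3, HCl    complete ionization (particles dissolve)
#   proteinaseK  partial ionization (half the particulate mass dissolves)
# Residue rates are scenario constants reflecting the reagents' tissue
# solubility (alkaline/enzymatic <= 10%, acids ~25%).

suppressPackageStartupMessages(library(spicpms))
dir.create("results", showWarnings = FALSE)

settings <- acquisition_settings()
calib <- fit_ionic_calibration(data.frame(
  concentration = c(0, 0.5, 1, 2, 5),
  mean_intensity = 500 * c(0, 0.5, 1, 2, 5)
))
eta <- transport_efficiency(0.05)
prep <- sample_prep(spike_concentration = 100, measurement_dilution = 500)

scenarios <- list(
  NaOH = list(transform = scenario_transform(dilution_factor = 500),
              residue = 5),
  TMAH = list(transform = scenario_transform(aggregated_fraction = 0.87,
                                             aggregate_order = 2,
                                             dilution_factor = 500),
              residue = 8),
  HNO3 = list(transform = scenario_transform(ionized_fraction = 1,
                                             dilution_factor = 500),
              residue = 25),
  HCl = list(transform = scenario_transform(ionized_fraction = 1,
                                            dilution_factor = 500),
             residue = 25),
  proteinaseK = list(transform = scenario_transform(ionized_fraction = 0.5,
                                                    dilution_factor = 500),
                     residue = 9)
)

spike_pop <- particle_population(
  100,
  number_concentration = 100 / (diameter_to_mass(100) * 1.0025^3 * 1e-6)
)

reports <- lapply(seq_along(scenarios), function(i) {
  sc <- scenarios[[i]]
  lapply(1:3, function(r) {
    sample <- apply_scenario(spike_pop, 0, sc$transform)
    tr <- simulate_trace(sample, settings = settings, seed = 100 * i + r)
    q <- quantify_sample(detect_events(tr), calib, eta, settings)
    recovery_rates(q, prep, residue = residue_rate(1, sc$residue / 100))
  })
})
names(reports) <- names(scenarios)

tab <- compare_reagents(reports)
write.csv(tab, "results/pretreatment_comparison.csv", row.names = FALSE)

for (i in seq_len(nrow(tab))) {
  message(sprintf(
    "%-12s residue %4.1f%%  particles %5.1f +/- %4.1f%%  ions %5.1f%%  diameter %s nm  FDA gate: %s",
    tab$reagent[i], tab$residue_rate_mean[i],
    tab$particle_recovery_mean[i],
    ifelse(is.na(tab$particle_recovery_sd[i]), 0, tab$particle_recovery_sd[i]),
    tab$ion_recovery_mean[i],
    ifelse(is.na(tab$mean_diameter_mean[i]), "--",
           sprintf("%.0f", tab$mean_diameter_mean[i])),
    ifelse(tab$fda_pass_all[i], "pass", "FAIL")
  ))
}
message("alkaline pretreatment keeps the spike particulate at ~100% recovery; acids convert it to ions; aggregation shifts and broadens the size distribution")
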