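# spicpms

Single-particle ICP-MS (sp-ICP-MS) signal processing in R: simulation of
time-resolved traces with known ground truth, particle event detection
over the ionic background, calibration, conversion of events to particle
sizes and concentrations, determination of the coincidence-limited
critical particle count, and the spike-recovery / particle–ion partition
metrics used to evaluate tissue pretreatment methods for nanoparticle
analysis.

## The problem

sp-ICP-MS reads a time-resolved elemental-MS trace — one intensity per
dwell window (10 ms; 3000 windows per 30 s acquisition) — in which each
nanoparticle reaching the plasma produces a discrete spike over the
steady Poisson background of the dissolved analyte. From one acquisition
the method yields, simultaneously:

- the **particle number concentration** from the spike rate,
  `N = n_events / (η · q · T)` (transport efficiency η, sample uptake
  q, acquisition time T);
- **particle masses and spherical-equivalent diameters** from spike
  intensities, via the mass-flux equivalence
  `m = I_net · η q τ / s` and `d = (6m / (π ρ))^(1/3)`
  (ionic sensitivity s in counts/dwell per ng/mL, dwell time τ,
  density ρ);
- the **dissolved concentration** from the background mean through the
  ionic calibration line.

Two practical questions dominate applications to biological tissue, and
this package implements the analyses behind both. First, *how many
particles per acquisition can be counted before coincidence (two
particles in one dwell window, read as one large particle) breaks
counting linearity?* — answered by a serial-dilution ladder and a
difference-curve procedure that reports the critical detected-particle
count (~500 per 30 s acquisition at 3000 windows). Second, *which
tissue-solubilizing pretreatment recovers spiked nanoparticles without
transforming them?* — answered by spike-recovery metrics that split the
recovered analyte into particulate and ionic pools, check the 80–120%
bioanalytical acceptance gate, and compare size distributions across
reagent scenarios (alkaline: unchanged; acidic: ionized; aggregating:
size distribution shifted and broadened).

No measured datasets exist for these analyses; a ground-truth simulator
(Poisson arrivals, lognormal diameters, Poisson counting noise,
coincidence by construction) stands in for the instrument, and every
result is parameter recovery against known truth.

## Worked example

Simulate a 100 nm silver suspension at ~300 events per acquisition,
detect, and quantify:

```r
library(spicpms)

settings <- acquisition_settings()     # 10 ms dwell, 30 s, η = 0.05
calib <- fit_ionic_calibration(data.frame(
  concentration = c(0, 0.5, 1, 2, 5),                 # ng/mL
  mean_intensity = 500 * c(0, 0.5, 1, 2, 5)           # counts/dwell
))
pop <- particle_population(
  100, number_concentration = number_conc_for_events(300, settings)
)
tr <- simulate_trace(pop, dissolved_conc = 0, settings, seed = 1)
q <- quantify_sample(detect_events(tr), calib,
                     transport_efficiency(0.05), settings)
q
#> <quant_result> 297 events
#>   number conc.      3.434e+04 particles/mL
#>   particulate mass  0.1979 ng/mL
#>   dissolved         0 ng/mL
#>   diameter          101 nm (median 100.2, sd 7.7), LOD 10.2 nm
```

297 detected events at a true expectation of 300 reflects Poisson
occupancy (a few windows hold two particles); the mean diameter sits
~1.5% above nominal because those coincident windows are read as single
larger particles — the bias the critical-count analysis bounds.

The full analyses are scripted:

```sh
Rscript analysis/01_linearity.R        # critical count from a 40-point ladder
Rscript analysis/02_size_validation.R  # 30/70/100 nm size recovery
Rscript analysis/03_pretreatment.R     # reagent scenario screen
Rscript analysis/04_invivo_partition.R # particle/ion partition scenarios
```

Each writes its tables under `results/` and prints a one-paragraph
summary, e.g. `01_linearity.R`:

```text
critical count over 20 seeds: 492 +/- 30 (range 427-536); analyses
should stay below ~500 events per acquisition
```

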