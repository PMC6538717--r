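---
title: "Signal model and methods of spicpms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal model and methods of spicpms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicpms)
```

# The measurement

Single-particle ICP-MS resolves individual nanoparticles in a
time-resolved elemental-MS trace. The instrument reports one intensity
per dwell window (10 ms here; 30 s acquisitions give 3000 windows). A
dissolved analyte concentration produces a steady Poisson background; a
nanoparticle that reaches the plasma within a window produces a discrete
spike on top of it. Counting spikes gives the particle number
concentration, their intensities give particle masses and
spherical-equivalent diameters, and the background mean gives the
dissolved concentration — so one acquisition quantifies both pools and
the size distribution at once.

Internal units are seconds, mL, ng, nm and fg, and every intensity is
counts per dwell window (never counts per second), so dwell-time
bookkeeping happens in exactly one place.

# The simulator

`simulate_trace()` is the stand-in for the instrument; no measured data
enter this package. Per dwell window of length $\tau$:

* background counts $\sim \mathrm{Poisson}(b + s\,C_\mathrm{diss})$,
  where $s$ is the ionic sensitivity (counts/dwell per ng/mL), $b$ the
  instrument background and $C_\mathrm{diss}$ the dissolved
  concentration;
* particle arrivals $\sim \mathrm{Poisson}(\lambda)$ with
  $\lambda = N \, q \, \eta \, \tau$, where $N$ is the number
  concentration, $q$ the sample uptake (mL/s) and $\eta$ the transport
  efficiency;
* each arrival draws a lognormal diameter $d$ (arithmetic mean and CV
  parameterization), carries analyte mass
  $m = \tfrac{\pi}{6}\rho d^3 f_m$, and contributes
  $\mathrm{Poisson}\!\big(m\,s / (\eta q \tau)\big)$ counts.

The last expression makes dissolved and particulate mass fluxes
strictly commensurable: a given mass reaching the plasma yields the same
expected counts either way, which is the identity the whole calculation
chain rests on. Contributions within a window sum, so two particles in
one window are indistinguishable from one large particle — coincidence,
the failure mode the critical-count analysis quantifies.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| dwell time | 0.010 s | reference acquisition |
| duration | 30 s | reference acquisition (3000 windows) |
| sample uptake | 0.346 mL/min | typical concentric-nebulizer uptake; illustrative, must be configured for a real instrument |
| transport efficiency | 0.05 | typical of unheated spray chambers; illustrative |
| ionic sensitivity | 500 counts/dwell/(ng/mL) | $5\times10^4$ cps per ng/mL, a typical silver sensitivity; puts a 30 nm Ag event at ~26 counts, well above a clean background |
| instrument background | 0 counts/dwell | clean-instrument reference condition |
| diameter CV | 0.05 | narrowly distributed commercial stocks |
| density | 10.49 g/cm^3 | metallic silver |

Most results depend on uptake and transport efficiency only through
their product $q\eta$ (the analyzed volume per unit time); both are
exposed because real calibrations determine them separately.

What the simulator deliberately omits: detector flicker/multiplicative
noise (counts are pure Poisson), split events (at 10 ms dwell an event
lasting well under a millisecond is assumed contained in one window; a
`merge_adjacent` toggle in detection serves shorter dwells), ionization
interferences, matrix effects on sensitivity, and any chemistry of the
pretreatment reagents. Pretreatment acts only through
`apply_scenario()`: an ionized fraction of the particulate mass moves to
the dissolved pool (removing the matching fraction of particles), an
aggregated fraction of the remaining particles merges into $k$-mers of
diameter $d\,k^{1/3}$, and everything is diluted. Mass is conserved
exactly before dilution. Passing tests therefore demonstrate the
correctness of the calculation chain under this idealized signal model,
not robustness to every artifact of real acquisitions.

# Event detection

`detect_events()` separates spikes from background by iterative outlier
rejection: starting from all windows, compute mean $\mu$ and sample
standard deviation $\sigma$ (n−1) of the current background set,
threshold at $\mu + k\sigma$ (default $k = 3$), drop every window
strictly above it, and repeat to a fixpoint. Strict comparison means a
constant trace yields no events. The dissolved signal is the mean of the
final background set.

Two properties of this estimator matter in practice:

* **Low backgrounds.** With a background of order 0.5 counts/dwell the
  Poisson tail itself crosses $\mu + 3\sigma$ in dozens of windows per
  3000; $k = 5$ is the appropriate setting for such traces.
* **Event-dominated traces.** A population of similar-intensity events
  occupying a fraction $f$ of the windows has standardized deviation
  $(1-f)/\sqrt{f(1-f)}$ in the whole-trace statistics; once this falls
  below $k$ (about $f > 0.10$ at $k = 3$) the iteration can stall and
  the detected count collapses far below the true occupancy. This is an
  inherent limitation of mean-based thresholding, and the reason
  sp-ICP-MS samples are diluted to a few hundred events per
  acquisition. The linearity analysis (below) detects and excludes such
  overloaded acquisitions rather than pretending they are valid counts:
  under Poisson occupancy the detected count is non-decreasing in
  concentration, and counting noise cannot nearly halve a count of 150
  or more, so a drop below 60% of the running maximum (when that
  maximum exceeds 150) marks a collapse unambiguously.

# Calibration and quantification

The ionic sensitivity comes from ordinary least squares on a dissolved
standard ladder (`fit_ionic_calibration()`). Transport efficiency uses
the particle-frequency method (`transport_efficiency_particle_frequency()`):
measure a particle standard of known number concentration and divide
detected events by delivered particles, $\eta = n / (N_\mathrm{ref}\,
q\,T)$. Because detected events are *occupied windows*, the method
recovers $\eta\,(1-e^{-\lambda})/\lambda$; the reference should be
dilute (the function warns when it is measured above the critical
count). The particle-size variant of the efficiency calibration is not
implemented.

Event masses invert the mass-flux identity:
$m = I_\mathrm{net}\,\eta q \tau / s$ with
$I_\mathrm{net} = I_\mathrm{raw} - \mu_\mathrm{bg}$. Subtracting the
background mean rather than the threshold keeps masses unbiased, at the
cost of a soft size floor; the floor is reported as `size_lod`, the
diameter at the smallest detectable net intensity
($\max(\mathrm{threshold} - \mu_\mathrm{bg}, 1)$ counts — one count
being the smallest resolvable excess on a zero background). Diameters
invert $m = \tfrac{\pi}{6}\rho d^3 f_m$. Number concentration is
events over analyzed volume $\eta q T$; the particulate mass
concentration sums event masses over the same volume; the dissolved
concentration is the background mean through the calibration line,
clipped at zero (negative raw values are reported via a message).

# Counting linearity and the critical count

At high particle rates coincidence makes the detected count fall below
the true arrival count: with Poisson arrivals the expected detected
count is the occupancy $n(1 - e^{-\lambda})$ of $n$ windows, while the
theoretical (coincidence-free) count is $n\lambda$. The analysis
simulates a 40-point serial-dilution ladder (starts 2000, 800, 700,
600 pg/mL, ten two-fold steps each — spanning roughly 0.6 to 2000
pg/mL), fits the theoretical line, and reports the largest detected
count whose relative shortfall
$(\mathrm{theoretical}-\mathrm{detected})/\mathrm{theoretical}$ stays
within a tolerance.

Design choices, each surfaced as a parameter:

* **Theoretical line.** The default estimator fits the occupancy model
  to the whole ladder by a binomial GLM with complementary log-log link
  and log-concentration offset and takes its linear limit $n\hat b$.
  The alternative low-region zero-intercept least-squares fit
  (`method = "linear"`) is retained, but on a single-trial ladder the
  lowest quartile holds only a few dozen counts in total, giving the
  slope ~14% sampling error — more than the tolerance itself — so it is
  not the default; it warns when the fitted region already shows
  saturation curvature.
* **Tolerance 0.085.** The shortfall $1-(1-e^{-\lambda})/\lambda$
  reaches 0.085 at $\lambda \approx 0.18$, where 3000 windows detect
  $\approx 495$ events. The tolerance, not the count, is the
  configuration: the ~500-event limit is a derived property of a 30 s /
  10 ms acquisition and moves with the window count.
* **Sustained, significant breaches.** The linear region ends at the
  first two consecutive samples whose shortfall exceeds the tolerance
  *and* whose absolute difference exceeds 3 counting standard errors
  ($3\sqrt{\mathrm{theoretical}}$). Without the significance guard,
  bottom-of-ladder samples with single-digit expected counts breach any
  fixed relative tolerance about half the time by shot noise alone, and
  paired 2-sigma dips at moderate counts fake an occasional early
  breach.
* **Interpolated crossing.** The ladder grid is coarse near the
  breakpoint (counts jump ~60 between adjacent solutions), so the
  critical count interpolates the shortfall crossing between the last
  in-tolerance and first over-tolerance samples instead of snapping to
  a grid point, which would bias it low by up to 13%.
* **Overload exclusion.** Samples past a detected-count collapse (see
  above) are excluded before fitting and scanning and are reported in
  `n_excluded`.

On noiseless occupancy counts the procedure returns ~495; across
simulated ladders it returns 492 ± 27 (40 seeds), comfortably inside a
±15% band around 500.

# Pretreatment metrics

`residue_rate()` is undissolved tissue mass as a percentage of initial
mass. `recovery_rates()` back-calculates measured concentrations to the
homogenate level (multiplying by the measurement dilution, 500 by
default) and expresses particulate and dissolved pools as percentages of
the known spike (100 ng/mL by default); the reagent's own 1:1 v/v
addition is treated as already reflected in the spike level, since that
is the level at which the spike concentration is defined. The 80–120%
bioanalytical acceptance interval is closed at both ends, and recoveries
above 100% are reported as-is. `partition()` splits total analyte into
particulate and ionic percentages (closing to 100 by construction), and
`compare_reagents()` reports mean ± sample SD (n−1) over replicates per
reagent, ordered by name. No hypothesis testing is performed between
reagents.

The in-vivo-style analysis (`analysis/04_invivo_partition.R`) recovers
*configured* ionized fractions from synthetic scenarios; it demonstrates
that the pipeline reads a particle/ion split correctly, not anything
about real tissues.

# Numerical and testing choices

Randomness is confined to `simulate_trace()` and derives entirely from
its `seed` argument (the caller's RNG state is saved and restored), so
identical inputs give bit-identical traces and every analysis is
reproducible from a single integer. Detection and all downstream
computations are deterministic. Trace files round-trip bit-exactly
(`%.17g` headers, integer counts). Validation failures are typed
conditions (`spicpms_validation_error`, `spicpms_degenerate_trace_error`,
and friends) rather than bare strings.

The test suite runs entirely on simulated data at deliberately modest
problem sizes — 3000-window traces, a few hundred events, 10–30 seeds
per Monte-Carlo assertion, 12 ladder seeds for the critical-count check —
chosen so statistical assertions operate at 3 standard errors with
stable margins while the whole suite stays fast. Closed-form oracles
(sphere mass, Poisson occupancy, hand-run detection iterations,
closed-form least squares) anchor the stochastic checks.

# Known limitations

* Mean + k-sigma detection requires background-dominated traces; above
  ~10% occupied windows at $k=3$ the detected count is unreliable (and
  flagged in the linearity analysis, but not repaired).
* The frequency-method transport efficiency carries the
  $(1-e^{-\lambda})/\lambda$ coincidence factor of its reference
  measurement.
* Scenario transforms are phenomenological bookkeeping on
  concentrations and diameters; they encode no reagent chemistry, and
  partial ionization removes whole particles rather than shrinking
  them.
* Split events, non-Poisson noise, matrix effects and vendor file
  formats are out of scope.
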