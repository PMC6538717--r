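# Synthetic sp-ICP-MS traces with known ground truth. The simulator is the
# stand-in for the instrument: Poisson particle arrivals per dwell window,
# lognormal particle diameters, per-event counts proportional to analyte
# mass, and a Poisson ionic background proportional to the dissolved
# concentration plus the instrument background.

# fg of analyte in a sphere of diameter d nm
sphere_mass_fg <- function(diameter_nm, density, mass_fraction = 1) {
  pi / 6 * density * diameter_nm^3 * 1e-6 * mass_fraction
}

# Expected analyte mass per particle of a lognormal population, fg.
# E[d^3] = mean^3 * (1 + cv^2)^3 for a lognormal with arithmetic mean and cv.
mean_particle_mass <- function(population) {
  stopifnot(inherits(population, "particle_population"))
  sphere_mass_fg(population$mean_diameter, population$density,
                 population$mass_fraction) *
    (1 + population$cv_diameter^2)^3
}

# lognormal parameters from arithmetic mean and cv
lognormal_params <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

as_population_list <- function(population) {
  if (inherits(population, "particle_population")) {
    return(list(population))
  }
  if (is.list(population) &&
      all(vapply(population, inherits, logical(1), "particle_population"))) {
    return(population)
  }
  if (inherits(population, "scenario_sample")) {
    return(population$populations)
  }
  validation_error(
    "`population` must be a particle_population or a list of them"
  )
}

#' Simulate one sp-ICP-MS time trace
#'
#' Generates a time-resolved trace of integer counts, one per dwell window.
#' Per window, the ionic background is
#' `Poisson(calib_intercept + calib_slope * dissolved_conc)` and the number
#' of arriving particles is `Poisson(lambda)` with
#' `lambda = number_concentration * sample_flow * transport_efficiency *
#' dwell_time`. Each arriving particle draws a lognormal diameter, is
#' converted to analyte mass, and contributes
#' `Poisson(mass * calib_slope / (transport_efficiency * sample_flow *
#' dwell_time))` counts, so that a given mass flux yields the same counts
#' whether it arrives dissolved or particulate. Contributions within a
#' window sum: two particles in one window are indistinguishable from one
#' large particle (coincidence), which is the failure mode the critical
#' particle count guards against.
#'
#' @param population A [particle_population()], a list of them (a mixture,
#'   e.g. from [apply_scenario()]), or a `scenario_sample`.
#' @param dissolved_conc Dissolved analyte concentration, ng/mL. Ignored
#'   (taken from the scenario) when `population` is a `scenario_sample`.
#' @param settings An [acquisition_settings()] object.
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   trace. `NULL` draws from the current RNG stream.
#'
#' @return An object of class `time_trace`: a list with `intensities`
#'   (integer counts per window), `settings`, and `truth` (the simulated
#'   populations, dissolved concentration, seed, total particle arrivals
#'   and occupied-window count).
#' @export
#' @examples
#' pop <- particle_population(100, number_concentration = 3.5e4)
#' tr <- simulate_trace(pop, dissolved_conc = 0,
#'                      settings = acquisition_settings(), seed = 1)
#' length(tr$intensities) # 3000
simulate_trace <- function(population, dissolved_conc = 0, settings,
                           seed = NULL) {
  if (inherits(population, "scenario_sample")) {
    dissolved_conc <- population$dissolved_conc
  }
  pops <- as_population_list(population)
  stopifnot(inherits(settings, "acquisition_settings"))
  check_number(dissolved_conc, "dissolved_conc", lower = 0)

  nw <- n_windows(settings)
  eta <- settings$transport_efficiency
  flow <- settings$sample_flow
  tau <- settings$dwell_time

  lambda <- vapply(
    pops,
    function(p) p$number_concentration * flow * eta * tau,
    numeric(1)
  )
  if (sum(lambda) * nw > 10 * nw) {
    validation_error(sprintf(
      "unphysical configuration: %.3g expected particles per dwell window",
      sum(lambda)
    ))
  }

  bg_rate <- settings$calib_intercept + settings$calib_slope * dissolved_conc
  # counts per fg of analyte delivered in one dwell window
  counts_per_fg <- settings$calib_slope * 1e-6 / (eta * flow * tau)

  with_seed(seed, {
    intensities <- stats::rpois(nw, bg_rate)
    occupied <- logical(nw)
    n_particles <- 0L
    for (i in seq_along(pops)) {
      p <- pops[[i]]
      arrivals <- stats::rpois(nw, lambda[[i]])
      k <- sum(arrivals)
      n_particles <- n_particles + k
      occupied <- occupied | arrivals > 0L
      if (k == 0L) next
      if (p$cv_diameter > 0) {
        lp <- lognormal_params(p$mean_diameter, p$cv_diameter)
        d <- stats::rlnorm(k, lp$meanlog, lp$sdlog)
      } else {
        d <- rep(p$mean_diameter, k)
      }
      mass <- sphere_mass_fg(d, p$density, p$mass_fraction)
      sig <- stats::rpois(k, mass * counts_per_fg)
      widx <- rep.int(seq_len(nw), arrivals)
      add <- rowsum(sig, widx)
      at <- as.integer(rownames(add))
      intensities[at] <- intensities[at] + as.integer(add)
    }
    structure(
      list(
        intensities = as.integer(intensities),
        settings = settings,
        truth = list(
          populations = pops,
          dissolved_conc = dissolved_conc,
          seed = seed,
          n_particles = n_particles,
          n_occupied_windows = sum(occupied),
          expected_particles = sum(lambda) * nw
        )
      ),
      class = "time_trace"
    )
  })
}

#' Apply a pretreatment scenario to a suspension
#'
#' Transforms a (population, dissolved concentration) pair the way a
#' pretreatment is modeled to act: `ionized_fraction` of the particulate
#' analyte mass moves to the dissolved pool (a matching fraction of the
#' particles is removed), `aggregated_fraction` of the remaining particles
#' is replaced by `aggregated_fraction / k` k-mers of diameter
#' `d * k^(1/3)`, and every concentration is divided by `dilution_factor`.
#' Total analyte mass is conserved exactly before dilution.
#'
#' @param population A [particle_population()].
#' @param dissolved_conc Dissolved analyte concentration, ng/mL.
#' @param transform A [scenario_transform()].
#'
#' @return An object of class `scenario_sample`: list with `populations`
#'   (monomers and, when aggregation is present, k-mers) and
#'   `dissolved_conc`, ready for [simulate_trace()].
#' @export
#' @examples
#' pop <- particle_population(100, number_concentration = 1e5)
#' acid <- scenario_transform(ionized_fraction = 1)
#' apply_scenario(pop, 0, acid)$dissolved_conc # all mass dissolved
apply_scenario <- function(population, dissolved_conc, transform) {
  stopifnot(inherits(population, "particle_population"),
            inherits(transform, "scenario_transform"))
  check_number(dissolved_conc, "dissolved_conc", lower = 0)

  p <- transform$ionized_fraction
  a <- transform$aggregated_fraction
  k <- transform$aggregate_order
  f <- transform$dilution_factor

  particulate_mass <- population$number_concentration *
    mean_particle_mass(population) * 1e-6 # ng/mL
  dissolved <- dissolved_conc + p * particulate_mass
  n_remaining <- population$number_concentration * (1 - p)

  pops <- list()
  n_mono <- n_remaining * (1 - a)
  if (n_mono > 0 || n_remaining == 0) {
    pops <- c(pops, list(particle_population(
      mean_diameter = population$mean_diameter,
      cv_diameter = population$cv_diameter,
      number_concentration = n_mono / f,
      density = population$density,
      mass_fraction = population$mass_fraction
    )))
  }
  n_kmer <- n_remaining * a / k
  if (n_kmer > 0) {
    pops <- c(pops, list(particle_population(
      mean_diameter = population$mean_diameter * k^(1 / 3),
      cv_diameter = population$cv_diameter,
      number_concentration = n_kmer / f,
      density = population$density,
      mass_fraction = population$mass_fraction
    )))
  }
  structure(
    list(populations = pops, dissolved_conc = dissolved / f),
    class = "scenario_sample"
  )
}

#' Total particulate analyte mass concentration of a scenario sample
#'
#' @param x A `scenario_sample`, `particle_population`, or list of
#'   populations.
#' @return Particulate analyte mass concentration, ng/mL.
#' @export
particulate_mass_conc <- function(x) {
  pops <- as_population_list(x)
  sum(vapply(
    pops,
    function(p) p$number_concentration * mean_particle_mass(p) * 1e-6,
    numeric(1)
  ))
}

#' Simulate a serial-dilution ladder
#'
#' Builds the concentration ladder used for the counting-linearity
#' experiment: each start concentration is serially diluted `n_steps - 1`
#' times by `step_factor`, and one trace is simulated per solution. Mass
#' concentrations are converted to number concentrations through the
#' population's mean particle mass.
#'
#' @param stock A [particle_population()] describing the stock (its
#'   `number_concentration` is ignored; concentrations come from
#'   `start_concs`).
#' @param start_concs Start mass concentrations, pg/mL.
#' @param n_steps Number of solutions per start concentration (the start
#'   itself counts as step 1). Default 10.
#' @param step_factor Dilution factor between consecutive steps. Default 2.
#' @param settings An [acquisition_settings()] object.
#' @param seed Integer seed for the whole series.
#'
#' @return A list of `time_trace` objects (length
#'   `length(start_concs) * n_steps`), each with `truth$mass_conc_pg`
#'   recording the prepared mass concentration.
#' @export
#' @examples
#' stock <- particle_population(100, number_concentration = 0, cv_diameter = 0)
#' traces <- simulate_dilution_series(
#'   stock, start_concs = c(2000, 800, 700, 600), n_steps = 2,
#'   settings = acquisition_settings(), seed = 1
#' )
#' length(traces) # 8
simulate_dilution_series <- function(stock, start_concs, n_steps = 10,
                                     step_factor = 2, settings, seed = NULL) {
  stopifnot(inherits(stock, "particle_population"))
  check_numeric_vector(start_concs, "start_concs", lower = 0)
  if (any(start_concs <= 0)) {
    validation_error("`start_concs` must be strictly positive")
  }
  check_number(n_steps, "n_steps", lower = 1, integer = TRUE)
  check_number(step_factor, "step_factor", lower = 1, lower_open = TRUE)

  mean_mass_fg <- mean_particle_mass(stock)
  with_seed(seed, {
    traces <- list()
    for (start in start_concs) {
      for (j in seq_len(n_steps)) {
        conc_pg <- start / step_factor^(j - 1)
        number_conc <- conc_pg * 1e-3 / (mean_mass_fg * 1e-6) # particles/mL
        pop <- particle_population(
          mean_diameter = stock$mean_diameter,
          cv_diameter = stock$cv_diameter,
          number_concentration = number_conc,
          density = stock$density,
          mass_fraction = stock$mass_fraction
        )
        tr <- simulate_trace(pop, dissolved_conc = 0, settings = settings,
                             seed = NULL)
        tr$truth$mass_conc_pg <- conc_pg
        traces[[length(traces) + 1L]] <- tr
      }
    }
    traces
  })
}

#' Number concentration equivalent to a target event count
#'
#' Convenience inverse of the arrival-rate formula: the number
#' concentration at which `n_events` particles are expected to arrive over
#' the whole acquisition.
#'
#' @param n_events Target expected number of particle arrivals.
#' @param settings An [acquisition_settings()] object.
#' @return Particles per mL.
#' @export
number_conc_for_events <- function(n_events, settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  check_number(n_events, "n_events", lower = 0)
  n_events / (settings$transport_efficiency * settings$sample_flow *
                settings$duration)
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf(
    "<time_trace> %d windows, %d total counts, %s particle arrivals\n",
    length(x$intensities), sum(x$intensities),
    if (is.null(x$truth)) "unknown" else format(x$truth$n_particles)
  ))
  invisible(x)
}
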