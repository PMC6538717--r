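# Pretreatment-evaluation metrics: residue rate, spike-recovery split into
# particulate and ionic silver, the 80-120% bioanalytical acceptance flag,
# particle/ion partition, and replicate summaries per reagent.

#' Tissue residue rate
#'
#' Undissolved tissue mass after pretreatment as a percentage of the
#' initial tissue mass; the solubility indicator used to compare
#' solubilizing reagents.
#'
#' @param initial_tissue_mass Initial tissue mass, g.
#' @param residue_mass Residue mass after treatment, g; must not exceed
#'   the initial mass.
#' @return Residue rate, percent.
#' @export
#' @examples
#' residue_rate(1.0, 0.05) # 5: >90% of the tissue dissolved
residue_rate <- function(initial_tissue_mass, residue_mass) {
  check_number(initial_tissue_mass, "initial_tissue_mass",
               lower = 0, lower_open = TRUE)
  check_number(residue_mass, "residue_mass", lower = 0)
  if (residue_mass > initial_tissue_mass) {
    validation_error("`residue_mass` exceeds `initial_tissue_mass`")
  }
  100 * residue_mass / initial_tissue_mass
}

#' Spike-recovery report for a pretreated sample
#'
#' Back-calculates the measured particulate and dissolved concentrations
#' to the homogenate level (multiplying by the measurement dilution) and
#' expresses them as percentages of the known spike. The total recovery is
#' flagged against the 80-120% bioanalytical acceptance interval (closed
#' at both ends; recoveries above 100% are legal and reported as-is).
#'
#' @param quant A `quant_result` for the measured (diluted) sample.
#' @param prep A [sample_prep()] with the spike concentration (at the
#'   homogenate level, ng/mL) and the measurement dilution.
#' @param residue A residue rate (percent) to carry along, or `NA`.
#' @return An object of class `recovery_report`: `residue_rate`,
#'   `particle_recovery`, `ion_recovery`, `total_recovery` (percent of
#'   spike), `mean_diameter`, `sd_diameter` (nm), `fda_pass`,
#'   `n_replicates` (1).
#' @export
recovery_rates <- function(quant, prep, residue = NA_real_) {
  stopifnot(inherits(quant, "quant_result"), inherits(prep, "sample_prep"))
  particulate <- quant$particulate_mass_concentration *
    prep$measurement_dilution
  dissolved <- quant$dissolved_concentration * prep$measurement_dilution
  particle_recovery <- 100 * particulate / prep$spike_concentration
  ion_recovery <- 100 * dissolved / prep$spike_concentration
  total <- particle_recovery + ion_recovery
  structure(
    list(
      residue_rate = residue,
      particle_recovery = particle_recovery,
      ion_recovery = ion_recovery,
      total_recovery = total,
      mean_diameter = quant$mean_diameter,
      sd_diameter = quant$sd_diameter,
      fda_pass = total >= 80 && total <= 120,
      n_replicates = 1L
    ),
    class = "recovery_report"
  )
}

#' Particle/ion partition of the total analyte
#'
#' Splits the total analyte mass concentration of a quantified sample into
#' its particulate and dissolved percentages.
#'
#' @param quant A `quant_result`.
#' @return An object of class `partition_result`: `particle_fraction` and
#'   `ion_fraction` (percent, summing to 100), `total_ag` (ng/mL, at the
#'   measured dilution level).
#' @export
#' @examples
#' # a sample measured as 80% particulate silver:
#' # partition(quant)$particle_fraction ~ 80
partition <- function(quant) {
  stopifnot(inherits(quant, "quant_result"))
  particulate <- quant$particulate_mass_concentration
  dissolved <- quant$dissolved_concentration
  total <- particulate + dissolved
  if (total <= 0) {
    spicpms_error("no analyte detected: particle/ion partition undefined",
                  "spicpms_undefined_partition_error")
  }
  structure(
    list(
      particle_fraction = 100 * particulate / total,
      ion_fraction = 100 * dissolved / total,
      total_ag = total
    ),
    class = "partition_result"
  )
}

#' Replicate summary table across reagents
#'
#' Mean and sample standard deviation (n - 1) of every numeric recovery
#' field, per reagent, with replicate counts. Rows are ordered by reagent
#' name so the output is deterministic.
#'
#' @param replicate_reports Named list: one entry per reagent, each a list
#'   of `recovery_report` objects (replicates).
#' @return A data frame with one row per reagent: `reagent`, `n`, and
#'   `<field>_mean` / `<field>_sd` for residue rate, particle, ion and
#'   total recovery and mean diameter, plus `fda_pass_all`. SDs are `NA`
#'   for single replicates.
#' @export
compare_reagents <- function(replicate_reports) {
  if (!is.list(replicate_reports) || length(replicate_reports) == 0L ||
      is.null(names(replicate_reports)) ||
      any(names(replicate_reports) == "")) {
    validation_error(
      "`replicate_reports` must be a non-empty named list of report lists"
    )
  }
  fields <- c("residue_rate", "particle_recovery", "ion_recovery",
              "total_recovery", "mean_diameter")
  rows <- lapply(sort(names(replicate_reports)), function(reagent) {
    reps <- replicate_reports[[reagent]]
    if (length(reps) == 0L ||
        !all(vapply(reps, inherits, logical(1), "recovery_report"))) {
      validation_error(sprintf(
        "reagent `%s` needs at least one recovery_report", reagent
      ))
    }
    out <- list(reagent = reagent, n = length(reps))
    for (f in fields) {
      v <- vapply(reps, function(r) as.numeric(r[[f]]), numeric(1))
      out[[paste0(f, "_mean")]] <- mean(v)
      out[[paste0(f, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else NA_real_
    }
    out$fda_pass_all <- all(vapply(reps, `[[`, logical(1), "fda_pass"))
    as.data.frame(out)
  })
  do.call(rbind, rows)
}
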