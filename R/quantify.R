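#' From angular responses to molecules per particle
#'
#' The estimation chain: a measured immobilization response divided by the
#' modeled full-monolayer response gives the covered fraction of the
#' detection spot; covered area over the per-particle footprint gives the
#' particle count; the analyte-binding response times a mass-conversion
#' constant (default 600 ng/cm^2 per degree) gives adsorbed mass per area;
#' times the spot area, total mass; via the molecular weight and the
#' Avogadro constant, a molecule count; divided by the particle count, the
#' molecules attached per particle.
#'
#' @name quantify
NULL

#' Avogadro constant (2019 SI exact value), 1/mol
#' @export
AVOGADRO <- 6.02214076e23

NM2_PER_CM2 <- 1e14

#' Circular SPR detection spot
#'
#' @param diameter_mm Laser spot diameter on the sensor, millimetres
#'   (default 1).
#' @return Object of class `detection_spot` with the area exposed in both
#'   nm^2 (`area_nm2`) and cm^2 (`area_cm2`).
#' @export
detection_spot <- function(diameter_mm = 1) {
  check_number(diameter_mm, "diameter_mm", lower = 0, allow_zero_lower = FALSE)
  r_nm <- diameter_mm * 1e6 / 2
  area_nm2 <- pi * r_nm^2
  structure(list(diameter_mm = diameter_mm,
                 area_nm2 = area_nm2,
                 area_cm2 = area_nm2 / NM2_PER_CM2),
            class = "detection_spot")
}

#' Peptide specification
#'
#' @param name Peptide label (e.g. `"6K-TRP2"`).
#' @param molecular_weight Molar mass in g/mol; > 0.
#' @param anchor Attachment moiety: `"polyK"` (hexalysine), `"CPP"`
#'   (Tat-derived cell-penetrating peptide) or `"none"`.
#' @return Object of class `peptide_spec`.
#' @export
peptide_spec <- function(name, molecular_weight,
                         anchor = c("none", "polyK", "CPP")) {
  check_number(molecular_weight, "molecular_weight", lower = 0,
               allow_zero_lower = FALSE)
  anchor <- match.arg(anchor)
  structure(list(name = as.character(name),
                 molecular_weight = molecular_weight,
                 anchor = anchor),
            class = "peptide_spec")
}

#' Steady-state measurement record for one peptide
#'
#' @param peptide A [peptide_spec()].
#' @param immobilization_response Plateau angular response of the particle
#'   immobilization step, degrees; >= 0.
#' @param binding_response Plateau angular response of the peptide binding
#'   step, degrees, reference-channel corrected (see
#'   [reference_subtract()]); >= 0.
#' @param analyte_concentration_uM Injected peptide concentration, metadata
#'   only (default 100).
#' @param reference_corrected Whether `binding_response` was
#'   reference-subtracted; recorded in the report.
#' @return Object of class `measurement_record`.
#' @export
measurement_record <- function(peptide, immobilization_response,
                               binding_response,
                               analyte_concentration_uM = 100,
                               reference_corrected = TRUE) {
  check_flag(inherits(peptide, "peptide_spec"),
             "peptide must be a peptide_spec")
  check_number(immobilization_response, "immobilization_response", lower = 0)
  check_number(binding_response, "binding_response", lower = 0)
  check_number(analyte_concentration_uM, "analyte_concentration_uM",
               lower = 0)
  structure(list(peptide = peptide,
                 immobilization_response = immobilization_response,
                 binding_response = binding_response,
                 analyte_concentration_uM = analyte_concentration_uM,
                 reference_corrected = isTRUE(reference_corrected)),
            class = "measurement_record")
}

#' Fraction of the detection spot covered with particles
#'
#' @param measured Measured immobilization response, degrees; >= 0.
#' @param max_monolayer Modeled full-monolayer response, degrees; > 0.
#' @return `measured / max_monolayer`, in `[0, 1]`.  A measured response
#'   exceeding the monolayer maximum violates the monolayer model and is an
#'   error.
#' @export
coverage_fraction <- function(measured, max_monolayer) {
  check_number(measured, "measured", lower = 0)
  check_number(max_monolayer, "max_monolayer", lower = 0,
               allow_zero_lower = FALSE)
  frac <- measured / max_monolayer
  if (frac > 1) {
    stop_sprcoat("measured response (", format(measured),
                 " deg) exceeds the full-monolayer response (",
                 format(max_monolayer),
                 " deg): coverage cannot exceed a monolayer",
                 class = "sprcoat_model_violation")
  }
  frac
}

#' Number of particles on the detection spot
#'
#' @param coverage Covered fraction of the spot, in `[0, 1]`.
#' @param spot A [detection_spot()].
#' @param footprint_nm2 Per-particle footprint area, nm^2; > 0.
#' @return Real-valued particle count `coverage * spot area / footprint`.
#' @export
particle_count <- function(coverage, spot, footprint_nm2) {
  check_number(coverage, "coverage", lower = 0, upper = 1)
  check_flag(inherits(spot, "detection_spot"),
             "spot must be a detection_spot")
  check_number(footprint_nm2, "footprint_nm2", lower = 0,
               allow_zero_lower = FALSE)
  coverage * spot$area_nm2 / footprint_nm2
}

#' Adsorbed mass per unit area from a binding response
#'
#' @param binding_response Reference-corrected plateau response, degrees.
#' @param k Mass conversion constant, ng/cm^2 per degree (default 600, the
#'   value appropriate for peptides on this instrument class).
#' @return Mass surface density in ng/cm^2.
#' @export
mass_per_area <- function(binding_response, k = 600) {
  check_number(binding_response, "binding_response", lower = 0)
  check_number(k, "k", lower = 0, allow_zero_lower = FALSE)
  k * binding_response
}

#' Total adsorbed mass on the detection spot
#'
#' @param mass_per_area_ng_cm2 Surface density, ng/cm^2.
#' @param spot A [detection_spot()].
#' @return Mass in ng.
#' @export
total_mass <- function(mass_per_area_ng_cm2, spot) {
  check_number(mass_per_area_ng_cm2, "mass_per_area_ng_cm2", lower = 0)
  check_flag(inherits(spot, "detection_spot"),
             "spot must be a detection_spot")
  mass_per_area_ng_cm2 * spot$area_cm2
}

#' Number of molecules in a given mass of peptide
#'
#' @param mass_ng Mass in nanograms.
#' @param peptide A [peptide_spec()].
#' @return Molecule count `(mass_ng * 1e-9 / MW) * N_A`.
#' @export
molecule_count <- function(mass_ng, peptide) {
  check_number(mass_ng, "mass_ng", lower = 0)
  check_flag(inherits(peptide, "peptide_spec"),
             "peptide must be a peptide_spec")
  mass_ng * 1e-9 / peptide$molecular_weight * AVOGADRO
}

#' Molecules attached per particle
#'
#' @param molecules Total molecule count on the spot.
#' @param particles Particle count on the spot; > 0.
#' @return `molecules / particles`.
#' @export
molecules_per_particle <- function(molecules, particles) {
  check_number(molecules, "molecules", lower = 0)
  if (!is.numeric(particles) || length(particles) != 1L ||
      !is.finite(particles) || particles <= 0) {
    stop_sprcoat("particle count must be > 0 to express a per-particle ",
                 "density (got ", format(particles), "); was any particle ",
                 "immobilized (non-zero immobilization response)?",
                 class = "sprcoat_validation_error")
  }
  molecules / particles
}

#' Run the full quantification chain for one peptide
#'
#' Composes the single-step operations end to end: coverage from the
#' immobilization response and the modeled monolayer maximum, particle count
#' from coverage, footprint and spot size, then mass per area, total mass,
#' molecule count and molecules per particle from the binding response.
#'
#' @param record A [measurement_record()].
#' @param particle A [particle_model()].
#' @param stack A [sensor_stack()]; used to model the full-monolayer
#'   response unless `max_monolayer` is supplied directly.
#' @param spot A [detection_spot()].
#' @param k Mass conversion constant, ng/cm^2 per degree.
#' @param max_monolayer Optional precomputed full-monolayer response in
#'   degrees; skips the optical model (useful when quantifying many records
#'   against one stack).
#' @return Object of class `quantification_result`: a list with fields
#'   `peptide`, `coverage_fraction`, `particle_count`,
#'   `particle_count_rounded`, `mass_per_area_ng_cm2`, `total_mass_ng`,
#'   `molecule_count`, `molecules_per_particle`, plus the intermediates
#'   `max_monolayer_deg`, `footprint_nm2`, `spot`, `k` and the input record.
#' @export
#' @examples
#' \donttest{
#' trp2 <- measurement_record(peptide_spec("6K-TRP2", 1944.4, "polyK"),
#'                            immobilization_response = 0.136 * 2.28,
#'                            binding_response = 301.6 / 600)
#' run_chain(trp2, particle_model(), bcg_sensor_stack())
#' }
run_chain <- function(record, particle, stack = NULL,
                      spot = detection_spot(), k = 600,
                      max_monolayer = NULL) {
  check_flag(inherits(record, "measurement_record"),
             "record must be a measurement_record")
  check_flag(inherits(particle, "particle_model"),
             "particle must be a particle_model")
  if (is.null(max_monolayer)) {
    check_flag(inherits(stack, "sensor_stack"),
               "either a sensor_stack or max_monolayer must be given")
    max_monolayer <- max_monolayer_response(stack, particle)
  }
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_sprcoat("step '", what, "': ", conditionMessage(e),
                   class = "sprcoat_chain_error")
    })
  }
  cov <- step("coverage_fraction",
              coverage_fraction(record$immobilization_response,
                                max_monolayer))
  n_part <- step("particle_count",
                 particle_count(cov, spot, particle$footprint_nm2))
  mpa <- step("mass_per_area", mass_per_area(record$binding_response, k))
  m_tot <- step("total_mass", total_mass(mpa, spot))
  n_mol <- step("molecule_count", molecule_count(m_tot, record$peptide))
  per_part <- if (n_mol == 0 && n_part == 0) 0 else {
    step("molecules_per_particle", molecules_per_particle(n_mol, n_part))
  }
  structure(
    list(peptide = record$peptide,
         coverage_fraction = cov,
         particle_count = n_part,
         particle_count_rounded = round_half_up(n_part),
         mass_per_area_ng_cm2 = mpa,
         total_mass_ng = m_tot,
         molecule_count = n_mol,
         molecules_per_particle = per_part,
         max_monolayer_deg = max_monolayer,
         footprint_nm2 = particle$footprint_nm2,
         spot = spot, k = k,
         record = record),
    class = "quantification_result"
  )
}

#' @export
print.quantification_result <- function(x, ...) {
  cat(sprintf("Quantification: %s (MW %.2f g/mol, anchor %s)\n",
              x$peptide$name, x$peptide$molecular_weight, x$peptide$anchor))
  cat(sprintf("  monolayer max response: %.3f deg\n", x$max_monolayer_deg))
  cat(sprintf("  coverage:               %.1f %%\n",
              100 * x$coverage_fraction))
  cat(sprintf("  particles on spot:      %s\n",
              format(x$particle_count_rounded, big.mark = ",")))
  cat(sprintf("  mass per area:          %.1f ng/cm^2\n",
              x$mass_per_area_ng_cm2))
  cat(sprintf("  total mass:             %.3f ng\n", x$total_mass_ng))
  cat(sprintf("  molecules:              %.2e\n", x$molecule_count))
  cat(sprintf("  molecules per particle: %.2e\n", x$molecules_per_particle))
  invisible(x)
}

#' Tabulate quantification results
#'
#' @param results A list of `quantification_result` objects.
#' @return A data frame with one row per peptide mirroring the printed
#'   report: coverage percent, particle count, ng/cm^2, ng, molecules,
#'   molecules per particle.
#' @export
quantification_table <- function(results) {
  check_flag(is.list(results) && length(results) >= 1L &&
               all(vapply(results, inherits, logical(1),
                          "quantification_result")),
             "results must be a non-empty list of quantification_result")
  do.call(rbind, lapply(results, function(r) {
    data.frame(peptide = r$peptide$name,
               anchor = r$peptide$anchor,
               molecular_weight = r$peptide$molecular_weight,
               coverage_percent = 100 * r$coverage_fraction,
               particles = r$particle_count_rounded,
               mass_per_area_ng_cm2 = r$mass_per_area_ng_cm2,
               total_mass_ng = r$total_mass_ng,
               molecules = r$molecule_count,
               molecules_per_particle = r$molecules_per_particle)
  }))
}
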