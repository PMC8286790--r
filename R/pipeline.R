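#' Execute a full quantification run
#'
#' Builds the sensor stack and particle model from a validated
#' configuration, models the full-monolayer response once, extracts plateau
#' responses (from sensorgram files where configured, applying
#' reference-channel subtraction), and runs the quantification chain for
#' every peptide.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   JSON configuration.
#' @return Object of class `run_report`: `table` (one row per peptide),
#'   `results` (list of `quantification_result`), `intermediates`
#'   (monolayer response, effective thickness, footprint, spot areas),
#'   `config` echo, `version`, and `warnings`.
#' @export
run_quantification <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  check_flag(inherits(config, "run_config"),
             "config must be a run_config or a path")

  stack <- if (is.null(config$stack_file)) bcg_sensor_stack()
           else read_sensor_stack(config$stack_file)
  particle <- particle_model(
    volume_um3 = config$particle$volume_um3,
    refractive_index = config$particle$refractive_index,
    packing = packing_parameters(config$particle$packing_fraction,
                                 config$particle$fill_factor)
  )
  spot <- detection_spot(config$spot_diameter_mm)
  warnings <- character()

  mono <- max_monolayer_response(stack, particle,
                                 angle_min = config$scan$angle_min,
                                 angle_max = config$scan$angle_max,
                                 step = config$scan$step)

  plateau_from_file <- function(active_file, reference_file, window, what,
                                name) {
    active <- read_sensorgram(active_file)
    if (!is.null(reference_file)) {
      active <- reference_subtract(active, read_sensorgram(reference_file))
    }
    if (is.null(window)) {
      # default: last quarter of the association span is treated as plateau
      tr <- range(active$time_s)
      window <- c(tr[1] + 0.75 * diff(tr), tr[2])
    }
    val <- steady_state_response(active, window)
    if (val < 0) {
      warnings <<- c(warnings, sprintf(
        "%s: %s plateau is negative (%.4f deg); clamped to 0", name, what,
        val))
      val <- 0
    }
    as.numeric(val)
  }

  results <- lapply(config$peptides, function(p) {
    imm <- p$immobilization_response_deg %||%
      plateau_from_file(p$immobilization_file, NULL,
                        p$immobilization_window_s, "immobilization", p$name)
    bind <- p$binding_response_deg %||%
      plateau_from_file(p$active_file, p$reference_file,
                        p$binding_window_s, "binding", p$name)
    rec <- measurement_record(
      peptide_spec(p$name, p$molecular_weight, p$anchor),
      immobilization_response = imm,
      binding_response = bind,
      reference_corrected = !is.null(p$reference_file) ||
        !is.null(p$binding_response_deg)
    )
    if (bind == 0) {
      warnings <<- c(warnings,
                     sprintf("%s: zero binding response; reporting zeros",
                             p$name))
    }
    run_chain(rec, particle, spot = spot, k = config$mass_conversion_k,
              max_monolayer = mono)
  })

  structure(
    list(table = quantification_table(results),
         results = results,
         intermediates = list(
           max_monolayer_response_deg = mono,
           effective_thickness_nm = particle$effective_thickness_nm,
           equivalent_diameter_nm = particle$equivalent_diameter_nm,
           footprint_nm2 = particle$footprint_nm2,
           spot_area_nm2 = spot$area_nm2,
           spot_area_cm2 = spot$area_cm2),
         config = config,
         version = as.character(utils::packageVersion("sprcoat")),
         warnings = warnings),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("sprcoat run report (v", x$version, ")\n", sep = "")
  cat(sprintf("  monolayer max response: %.4f deg\n",
              x$intermediates$max_monolayer_response_deg))
  cat(sprintf("  effective thickness:    %.1f nm\n",
              x$intermediates$effective_thickness_nm))
  cat(sprintf("  footprint:              %.0f nm^2\n",
              x$intermediates$footprint_nm2))
  print(x$table)
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `report.tsv` (the per-peptide table) and `report.json` (the table
#' plus every intermediate, the configuration echo and warnings).  Output is
#' deterministic: the same configuration and seed produce byte-identical
#' files.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory, created if needed.
#' @return Paths of the written files, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  check_flag(inherits(report, "run_report"), "report must be a run_report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(out_dir, "report.tsv")
  jsn <- file.path(out_dir, "report.json")
  utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- unclass(report$config)
  cfg$config_path <- NULL  # keep reports relocatable and reproducible
  jsonlite::write_json(
    list(version = report$version,
         intermediates = report$intermediates,
         table = report$table,
         config = cfg,
         warnings = report$warnings),
    jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(tsv = tsv, json = jsn))
}

#' Generate two-channel synthetic sensorgram files
#'
#' Reads a simulation configuration (Langmuir parameters, injection
#' schedule, noise level, bulk shift, seed) and writes an active-channel
#' file (binding plus bulk shift) and a reference-channel file (bulk shift
#' only), directly usable as `active_file` / `reference_file` entries of a
#' run configuration.
#'
#' @param sim_config Path to a JSON simulation config, or an equivalent
#'   named list.  Keys: `k_on`, `k_off`, `R_max_deg`, `noise_sd_deg`,
#'   `bulk_shift_deg`, `dt_s`, `seed`, and a `schedule` object with
#'   `start_s`, `association_s`, `dissociation_s`, `concentration_uM`.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the config value.
#' @return Named character vector with the `active` and `reference` file
#'   paths, invisibly.
#' @export
simulate_command <- function(sim_config, out_dir, seed = NULL) {
  if (is.character(sim_config)) {
    check_flag(file.exists(sim_config), "sim config not found: ", sim_config)
    sim_config <- jsonlite::fromJSON(sim_config, simplifyDataFrame = FALSE)
  }
  sc <- sim_config$schedule %||% list()
  schedule <- injection_schedule(
    start_s = sc$start_s %||% 60,
    association_s = sc$association_s %||% 720,
    dissociation_s = sc$dissociation_s %||% 180,
    concentration_M = (sc$concentration_uM %||% 100) * 1e-6
  )
  params <- langmuir_parameters(sim_config$k_on %||% 1e4,
                                sim_config$k_off %||% 1e-3,
                                sim_config$R_max_deg %||% 0.6)
  noise_sd <- sim_config$noise_sd_deg %||% 0
  bulk <- sim_config$bulk_shift_deg %||% 0
  dt <- sim_config$dt_s %||% 1
  seed <- seed %||% sim_config$seed %||% 1
  seed <- as.integer(seed)

  active <- simulate_sensorgram(params, schedule, noise_sd = noise_sd,
                                seed = seed, dt = dt,
                                bulk_shift_deg = bulk, channel = "active")
  none <- langmuir_parameters(0, 0, 0)
  reference <- simulate_sensorgram(none, schedule, noise_sd = noise_sd,
                                   seed = seed + 1L, dt = dt,
                                   bulk_shift_deg = bulk,
                                   channel = "reference")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(active = file.path(out_dir, "active.tsv"),
             reference = file.path(out_dir, "reference.tsv"))
  write_sensorgram(active, paths[["active"]])
  write_sensorgram(reference, paths[["reference"]])
  invisible(paths)
}
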