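#' Run configuration
#'
#' A quantification run is described by a JSON file: the sensor stack (file
#' path, or the built-in default), the particle model, the detection-spot
#' diameter, the mass conversion constant, a seed, and one entry per peptide
#' giving its name, molecular weight, anchor, and either plateau responses
#' in degrees or sensorgram file paths with plateau windows.  Validation
#' collects every failure and reports them together, each with its key path.
#'
#' @param path Path to a JSON run configuration.
#' @return A validated `run_config` object with all defaults resolved.
#' @export
validate_config <- function(path) {
  check_flag(is.character(path) && length(path) == 1L && file.exists(path),
             "config file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e) {
                    stop_sprcoat("config is not valid JSON: ",
                                 conditionMessage(e),
                                 class = "sprcoat_config_error")
                  })
  base_dir <- dirname(normalizePath(path))
  errs <- character()
  note <- function(key, msg) errs[[length(errs) + 1L]] <<- paste0(key, ": ", msg)

  num_field <- function(x, key, default = NULL, lower = 0,
                        strict = TRUE) {
    if (is.null(x)) {
      if (is.null(default)) { note(key, "missing"); return(NA_real_) }
      return(default)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      note(key, "must be a single finite number"); return(NA_real_)
    }
    if ((strict && x <= lower) || (!strict && x < lower)) {
      note(key, paste0("must be ", if (strict) "> " else ">= ", lower,
                       " (got ", x, ")"))
      return(NA_real_)
    }
    x
  }
  resolve_file <- function(p, key) {
    if (is.null(p)) return(NULL)
    fp <- if (grepl("^/", p)) p else file.path(base_dir, p)
    if (!file.exists(fp)) note(key, paste0("file not found: ", p))
    fp
  }

  stack_file <- resolve_file(raw$stack_file, "stack_file")

  pa <- raw$particle %||% list()
  packing_fraction <- num_field(pa$packing_fraction, "particle.packing_fraction", 0.74)
  fill_factor <- num_field(pa$fill_factor, "particle.fill_factor", 0.524)
  refractive_index <- num_field(pa$refractive_index, "particle.refractive_index", 1.35)
  volume_um3 <- NULL
  if (!is.null(pa$volume_um3)) {
    volume_um3 <- num_field(pa$volume_um3, "particle.volume_um3")
  } else if (!is.null(pa$length_um) || !is.null(pa$width_um)) {
    L <- num_field(pa$length_um, "particle.length_um")
    w <- num_field(pa$width_um, "particle.width_um")
    shape <- pa$shape_model %||% "spherocylinder"
    if (!shape %in% c("cylinder", "spherocylinder", "ellipsoid")) {
      note("particle.shape_model", paste0("unknown shape model: ", shape))
    } else if (is.finite(L) && is.finite(w)) {
      if (L < w) note("particle", "length_um must be >= width_um")
      else volume_um3 <- rod_volume(rod_dimensions(L, w), shape)
    }
  } else {
    volume_um3 <- 0.3887  # canonical BCG single-cell volume
  }

  spot_diameter_mm <- num_field(raw$spot_diameter_mm, "spot_diameter_mm", 1)
  mass_conversion_k <- num_field(raw$mass_conversion_k, "mass_conversion_k", 600)
  seed <- num_field(raw$seed, "seed", 1, lower = -Inf)

  sc <- raw$scan %||% list()
  scan <- list(angle_min = num_field(sc$angle_min, "scan.angle_min", 55),
               angle_max = num_field(sc$angle_max, "scan.angle_max", 78),
               step = num_field(sc$step, "scan.step", 0.005))

  peptides <- raw$peptides
  if (is.null(peptides) || !is.list(peptides) || !length(peptides)) {
    note("peptides", "at least one peptide entry is required")
    peptides <- list()
  }
  seen <- character()
  peptides <- lapply(seq_along(peptides), function(i) {
    p <- peptides[[i]]
    key <- paste0("peptides[", i, "]")
    nm <- p$name
    if (is.null(nm) || !nzchar(nm)) { note(paste0(key, ".name"), "missing"); nm <- paste0("peptide", i) }
    if (nm %in% seen) note(paste0(key, ".name"), paste0("duplicate name: ", nm))
    seen <<- c(seen, nm)
    mw <- num_field(p$molecular_weight, paste0(key, ".molecular_weight"))
    anchor <- p$anchor %||% "none"
    if (!anchor %in% c("none", "polyK", "CPP")) {
      note(paste0(key, ".anchor"), paste0("must be none/polyK/CPP, got ", anchor))
      anchor <- "none"
    }
    imm <- NULL; bind <- NULL
    imm_file <- resolve_file(p$immobilization_file, paste0(key, ".immobilization_file"))
    act_file <- resolve_file(p$active_file, paste0(key, ".active_file"))
    ref_file <- resolve_file(p$reference_file, paste0(key, ".reference_file"))
    if (is.null(imm_file)) {
      imm <- num_field(p$immobilization_response_deg,
                       paste0(key, ".immobilization_response_deg"),
                       lower = 0, strict = FALSE)
    }
    if (is.null(act_file)) {
      bind <- num_field(p$binding_response_deg,
                        paste0(key, ".binding_response_deg"),
                        lower = 0, strict = FALSE)
    }
    win <- function(w, wkey) {
      if (is.null(w)) return(NULL)
      w <- unlist(w)
      if (!is.numeric(w) || length(w) != 2L || w[1] >= w[2]) {
        note(wkey, "must be [t0, t1] with t0 < t1"); return(NULL)
      }
      w
    }
    list(name = nm, molecular_weight = mw, anchor = anchor,
         immobilization_response_deg = imm,
         binding_response_deg = bind,
         immobilization_file = imm_file,
         immobilization_window_s = win(p$immobilization_window_s,
                                       paste0(key, ".immobilization_window_s")),
         active_file = act_file,
         reference_file = ref_file,
         binding_window_s = win(p$binding_window_s,
                                paste0(key, ".binding_window_s")))
  })

  if (length(errs)) {
    stop_sprcoat("invalid run configuration:\n  ",
                 paste(errs, collapse = "\n  "),
                 class = "sprcoat_config_error")
  }
  structure(
    list(stack_file = stack_file,
         particle = list(volume_um3 = volume_um3,
                         refractive_index = refractive_index,
                         packing_fraction = packing_fraction,
                         fill_factor = fill_factor),
         spot_diameter_mm = spot_diameter_mm,
         mass_conversion_k = mass_conversion_k,
         seed = as.integer(seed),
         scan = scan,
         peptides = peptides,
         config_path = normalizePath(path)),
    class = "run_config"
  )
}
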