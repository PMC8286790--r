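#' Default BCG assay sensor stack
#'
#' The Au-SiO2 multi-parametric SPR slide used for the BCG coating assay,
#' probed at 670 nm through a BK7 coupling prism with PBS as the ambient
#' buffer.  Layer constants are typical literature values for this slide
#' type; the gold extinction coefficient (3.515, within the 3.4--3.8 spread
#' of published values for Au at 670 nm) is calibrated once so that a full
#' hexagonally packed BCG monolayer -- a homogeneous slab of n = 1.35 and
#' thickness 351.1 nm -- produces the reference maximum angular response of
#' 2.28 degrees.  Every constant can be overridden, or a different stack
#' loaded from file with [read_sensor_stack()].
#'
#' @param prism_n Coupling prism refractive index (BK7 at 670 nm).
#' @param cr_thickness_nm,cr_n Chromium adhesion layer.
#' @param au_thickness_nm,au_n Gold plasmonic layer.
#' @param sio2_thickness_nm,sio2_n Silica top coat.
#' @param ambient_n Running-buffer (PBS) refractive index.
#' @param wavelength_nm Laser vacuum wavelength.
#' @return A [sensor_stack()].
#' @export
#' @examples
#' bcg_sensor_stack()
bcg_sensor_stack <- function(prism_n = 1.5151,
                             cr_thickness_nm = 2,
                             cr_n = complex(real = 3.0, imaginary = 3.5),
                             au_thickness_nm = 50,
                             au_n = complex(real = 0.14, imaginary = 3.515),
                             sio2_thickness_nm = 15,
                             sio2_n = 1.456,
                             ambient_n = 1.335,
                             wavelength_nm = 670) {
  sensor_stack(list(
    optical_layer("prism", prism_n),
    optical_layer("Cr", cr_n, cr_thickness_nm),
    optical_layer("Au", au_n, au_thickness_nm),
    optical_layer("SiO2", sio2_n, sio2_thickness_nm),
    optical_layer("ambient", ambient_n)
  ), wavelength_nm = wavelength_nm)
}

#' Read / write a sensor stack description file
#'
#' The file is JSON with a `wavelength_nm` scalar and a `layers` array whose
#' entries carry `name`, `n_real`, `n_imag` and `thickness_nm` (`null` for
#' the two bounding half-spaces).  An example describing the BCG assay slide
#' ships as `system.file("extdata", "bcg_sensor.json", package = "sprcoat")`.
#'
#' @param path File path.
#' @return `read_sensor_stack()` returns a [sensor_stack()];
#'   `write_sensor_stack()` returns `path` invisibly.
#' @export
read_sensor_stack <- function(path) {
  check_flag(file.exists(path), "stack file not found: ", path)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  check_flag(!is.null(spec$layers), "stack file lacks a 'layers' array")
  layers <- lapply(spec$layers, function(ly) {
    check_flag(!is.null(ly$name) && !is.null(ly$n_real),
               "each layer needs 'name' and 'n_real'")
    optical_layer(ly$name,
                  complex(real = ly$n_real, imaginary = ly$n_imag %||% 0),
                  thickness_nm = ly$thickness_nm %||% NA_real_)
  })
  sensor_stack(layers, wavelength_nm = spec$wavelength_nm %||% 670)
}

#' @param stack A [sensor_stack()] to serialize.
#' @rdname read_sensor_stack
#' @export
write_sensor_stack <- function(stack, path) {
  check_flag(inherits(stack, "sensor_stack"), "stack must be a sensor_stack")
  layers <- lapply(stack$layers, function(ly) {
    list(name = ly$name,
         n_real = Re(ly$refractive_index),
         n_imag = Im(ly$refractive_index),
         thickness_nm = if (is.na(ly$thickness_nm)) NULL else ly$thickness_nm)
  })
  jsonlite::write_json(list(wavelength_nm = stack$wavelength_nm,
                            layers = layers),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
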