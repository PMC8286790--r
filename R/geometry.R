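#' Particle geometry and packing models
#'
#' Rod-shaped bacteria such as BCG are represented on the sensor as an
#' equivalent sphere of the same volume.  A full monolayer of such spheres,
#' hexagonally close packed, is then collapsed into an effective homogeneous
#' slab whose thickness feeds the optical model.  Two packing constants
#' control the collapse: the fraction of the sensor plane that packed
#' particles can occupy (default 0.74) and the sphere-to-slab volume fill
#' factor (default 0.524).
#'
#' @name geometry
NULL

#' Packing parameters for a close-packed particle monolayer
#'
#' @param area_packing_fraction Fraction of the sensor plane that can be
#'   covered by packed particles; in (0, 1]. Default 0.74.
#' @param volume_fill_factor Factor converting the packed-sphere layer into a
#'   homogeneous slab of equal material volume; in (0, 1]. Default 0.524,
#'   the sphere-to-circumscribing-cube volume ratio (pi/6).
#' @return An object of class `packing_parameters`.
#' @export
#' @examples
#' packing_parameters()           # defaults used for the BCG monolayer
#' packing_parameters(1, 1)       # no packing correction
packing_parameters <- function(area_packing_fraction = 0.74,
                               volume_fill_factor = 0.524) {
  check_number(area_packing_fraction, "area_packing_fraction",
               lower = 0, upper = 1, allow_zero_lower = FALSE)
  check_number(volume_fill_factor, "volume_fill_factor",
               lower = 0, upper = 1, allow_zero_lower = FALSE)
  structure(
    list(area_packing_fraction = area_packing_fraction,
         volume_fill_factor = volume_fill_factor),
    class = "packing_parameters"
  )
}

#' Rod dimensions of a bacillus
#'
#' @param length_um Cell length in micrometres; must be >= width.
#' @param width_um Cell width (diameter) in micrometres; > 0.
#' @return An object of class `rod_dimensions`.
#' @export
rod_dimensions <- function(length_um, width_um) {
  check_number(length_um, "length_um", lower = 0, allow_zero_lower = FALSE)
  check_number(width_um, "width_um", lower = 0, allow_zero_lower = FALSE)
  check_flag(length_um >= width_um,
             "length_um (", length_um, ") must be >= width_um (", width_um, ")")
  structure(list(length_um = length_um, width_um = width_um),
            class = "rod_dimensions")
}

#' Volume of a rod-shaped cell under a chosen shape model
#'
#' Three standard idealizations of a bacillus are supported:
#' a straight cylinder pi r^2 L, a spherocylinder (cylinder with
#' hemispherical caps) pi r^2 (L - w) + 4/3 pi r^3, and a prolate
#' ellipsoid (pi/6) L w^2, where r = w / 2.
#'
#' @param dims A [rod_dimensions()] object (or length/width given directly).
#' @param shape_model One of `"cylinder"`, `"spherocylinder"`, `"ellipsoid"`.
#' @return Volume in cubic micrometres.
#' @export
#' @examples
#' rod_volume(rod_dimensions(2.36, 0.47), "spherocylinder")
rod_volume <- function(dims, shape_model = c("cylinder", "spherocylinder",
                                             "ellipsoid")) {
  if (!inherits(dims, "rod_dimensions")) {
    stop_sprcoat("dims must be a rod_dimensions object",
                 class = "sprcoat_validation_error")
  }
  shape_model <- match.arg(shape_model)
  L <- dims$length_um
  w <- dims$width_um
  r <- w / 2
  switch(shape_model,
    cylinder = pi * r^2 * L,
    spherocylinder = pi * r^2 * (L - w) + (4 / 3) * pi * r^3,
    ellipsoid = (pi / 6) * L * w^2
  )
}

#' Diameter of the sphere with a given volume
#'
#' @param volume_um3 Particle volume in cubic micrometres; > 0.
#' @return Equivalent-sphere diameter in nanometres:
#'   `1000 * (6 V / pi)^(1/3)`.
#' @export
#' @examples
#' equivalent_sphere_diameter(0.3887)  # BCG: 905.5 nm
equivalent_sphere_diameter <- function(volume_um3) {
  check_number(volume_um3, "volume_um3", lower = 0, allow_zero_lower = FALSE)
  1000 * (6 * volume_um3 / pi)^(1 / 3)
}

#' Effective homogeneous thickness of a packed-sphere monolayer
#'
#' The sphere diameter is scaled by the in-plane packing fraction and then by
#' the volume fill factor, yielding the thickness of the homogeneous slab
#' assumed by the optical model.
#'
#' @param diameter_nm Equivalent-sphere diameter in nanometres; > 0.
#' @param packing A [packing_parameters()] object.
#' @return Slab thickness in nanometres.
#' @export
#' @examples
#' effective_layer_thickness(905.5)  # 351.1 nm for the BCG defaults
effective_layer_thickness <- function(diameter_nm,
                                      packing = packing_parameters()) {
  check_number(diameter_nm, "diameter_nm", lower = 0, allow_zero_lower = FALSE)
  if (!inherits(packing, "packing_parameters")) {
    stop_sprcoat("packing must be a packing_parameters object",
                 class = "sprcoat_validation_error")
  }
  diameter_nm * packing$area_packing_fraction * packing$volume_fill_factor
}

#' Projected footprint area of a spherical particle
#'
#' @param diameter_nm Particle diameter in nanometres; > 0.
#' @return Projected circular area `pi (d/2)^2` in square nanometres.
#' @export
#' @examples
#' footprint_area(905.5)  # ~643,971 nm^2
footprint_area <- function(diameter_nm) {
  check_number(diameter_nm, "diameter_nm", lower = 0, allow_zero_lower = FALSE)
  pi * (diameter_nm / 2)^2
}

#' Particle model for monolayer quantification
#'
#' Bundles the particle volume (given directly, or derived from rod
#' dimensions through [rod_volume()]), its equivalent-sphere diameter,
#' refractive index, and packing constants.  The shipped defaults describe
#' a BCG bacterium: volume 0.3887 um^3 (equivalent diameter 905.5 nm) and
#' refractive index 1.35.
#'
#' @param volume_um3 Single-cell volume in cubic micrometres.  The default
#'   0.3887 is the canonical BCG value; supply [rod_volume()] output to use
#'   an explicit shape model instead.
#' @param refractive_index Real refractive index of the particle material.
#' @param packing A [packing_parameters()] object.
#' @return An object of class `particle_model` with fields `volume_um3`,
#'   `equivalent_diameter_nm`, `refractive_index`, `packing`, and the
#'   derived `effective_thickness_nm` and `footprint_nm2`.
#' @export
#' @examples
#' bcg <- particle_model()
#' bcg$equivalent_diameter_nm  # 905.5
#' bcg$effective_thickness_nm  # 351.1
particle_model <- function(volume_um3 = 0.3887,
                           refractive_index = 1.35,
                           packing = packing_parameters()) {
  check_number(volume_um3, "volume_um3", lower = 0, allow_zero_lower = FALSE)
  check_number(refractive_index, "refractive_index",
               lower = 0, allow_zero_lower = FALSE)
  d <- equivalent_sphere_diameter(volume_um3)
  structure(
    list(volume_um3 = volume_um3,
         equivalent_diameter_nm = d,
         refractive_index = refractive_index,
         packing = packing,
         effective_thickness_nm = effective_layer_thickness(d, packing),
         footprint_nm2 = footprint_area(d)),
    class = "particle_model"
  )
}

#' @export
print.particle_model <- function(x, ...) {
  cat("Particle model\n")
  cat(sprintf("  volume:              %.4f um^3\n", x$volume_um3))
  cat(sprintf("  equivalent diameter: %.1f nm\n", x$equivalent_diameter_nm))
  cat(sprintf("  refractive index:    %.3f\n", x$refractive_index))
  cat(sprintf("  packing fraction:    %.3f, fill factor: %.3f\n",
              x$packing$area_packing_fraction,
              x$packing$volume_fill_factor))
  cat(sprintf("  effective thickness: %.1f nm\n", x$effective_thickness_nm))
  cat(sprintf("  footprint:           %.0f nm^2\n", x$footprint_nm2))
  invisible(x)
}
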