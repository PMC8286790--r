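#' Multilayer SPR optics
#'
#' p-polarized reflectance of a stratified sensor stack in the Kretschmann
#' configuration, computed with the characteristic (transfer) matrix method,
#' plus localization of the surface-plasmon resonance dip and the angular
#' response (dip shift) produced by an adsorbed layer.
#'
#' Conventions: the incidence angle is the internal angle in the coupling
#' half-space (prism), in degrees.  Complex refractive indices are written
#' n + ik with k >= 0 for absorbing media (time dependence exp(-i omega t));
#' evanescent fields decay away from each interface.
#'
#' @name optics
NULL

#' An optical layer of the sensor stack
#'
#' @param name Layer label.
#' @param refractive_index Complex (or real) refractive index; real part > 0,
#'   non-negative imaginary part for absorbing media.
#' @param thickness_nm Thickness in nanometres; `NA` (the default) marks a
#'   semi-infinite bounding half-space.
#' @return An object of class `optical_layer`.
#' @export
optical_layer <- function(name, refractive_index, thickness_nm = NA_real_) {
  n <- as.complex(refractive_index)
  check_flag(length(n) == 1L && is.finite(Re(n)) && Re(n) > 0,
             "refractive_index must have a positive real part")
  check_flag(Im(n) >= 0, "extinction (imaginary index) must be >= 0")
  if (!is.na(thickness_nm)) {
    check_number(thickness_nm, "thickness_nm", lower = 0)
  }
  structure(list(name = as.character(name), refractive_index = n,
                 thickness_nm = as.numeric(thickness_nm)),
            class = "optical_layer")
}

#' A layered SPR sensor stack
#'
#' Layers are ordered from the coupling half-space (prism side) to the
#' ambient half-space (buffer side).  The first and last layers must be
#' half-spaces (no thickness); interior layers must have finite thickness.
#'
#' @param layers List of [optical_layer()] objects, at least two.
#' @param wavelength_nm Vacuum wavelength in nanometres (default 670, the
#'   red diode laser typical of multi-parametric SPR instruments).
#' @return An object of class `sensor_stack`.
#' @export
sensor_stack <- function(layers, wavelength_nm = 670) {
  check_flag(is.list(layers) && length(layers) >= 2L &&
               all(vapply(layers, inherits, logical(1), "optical_layer")),
             "layers must be a list of >= 2 optical_layer objects")
  check_number(wavelength_nm, "wavelength_nm", lower = 0,
               allow_zero_lower = FALSE)
  nl <- length(layers)
  check_flag(is.na(layers[[1]]$thickness_nm),
             "first layer must be a half-space (thickness NA)")
  check_flag(is.na(layers[[nl]]$thickness_nm),
             "last layer must be a half-space (thickness NA)")
  if (nl > 2L) {
    interior <- layers[2:(nl - 1L)]
    check_flag(all(!is.na(vapply(interior, `[[`, numeric(1), "thickness_nm"))),
               "interior layers must have finite thickness")
  }
  check_flag(Im(layers[[1]]$refractive_index) == 0,
             "coupling half-space must be lossless")
  structure(list(layers = layers, wavelength_nm = wavelength_nm),
            class = "sensor_stack")
}

#' @export
print.sensor_stack <- function(x, ...) {
  cat(sprintf("SPR sensor stack (wavelength %.1f nm)\n", x$wavelength_nm))
  for (ly in x$layers) {
    th <- if (is.na(ly$thickness_nm)) "half-space"
          else sprintf("%8.2f nm", ly$thickness_nm)
    n <- ly$refractive_index
    cat(sprintf("  %-10s n = %.4f%+.4fi  %s\n", ly$name, Re(n), Im(n), th))
  }
  invisible(x)
}

# z-component of the wavevector in each layer for in-plane component kx,
# with the decaying branch (Im >= 0; Re >= 0 when purely real)
kz_branch <- function(n, k0, kx) {
  kz <- sqrt(as.complex((k0 * n)^2 - kx^2))
  flip <- Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

#' p-polarized reflectance of a sensor stack
#'
#' Characteristic-matrix computation of |r_p|^2 at the given internal
#' incidence angle(s) in the coupling half-space.
#'
#' @param stack A [sensor_stack()].
#' @param angle_deg Internal incidence angle(s) in degrees, each in (0, 90).
#' @return Reflectance in `[0, 1]`, one value per angle.
#' @export
#' @examples
#' prism <- optical_layer("prism", 1.515)
#' water <- optical_layer("water", 1.335)
#' reflectance_p(sensor_stack(list(prism, water)), 75)  # beyond TIR: 1
reflectance_p <- function(stack, angle_deg) {
  check_flag(inherits(stack, "sensor_stack"), "stack must be a sensor_stack")
  check_flag(is.numeric(angle_deg) && length(angle_deg) >= 1L &&
               all(is.finite(angle_deg)) &&
               all(angle_deg > 0 & angle_deg < 90),
             "angle_deg must lie in (0, 90) degrees")
  layers <- stack$layers
  nl <- length(layers)
  k0 <- 2 * pi / stack$wavelength_nm
  n1 <- Re(layers[[1]]$refractive_index)
  theta <- angle_deg * pi / 180
  kx <- k0 * n1 * sin(theta)

  # p-polarization admittance q_j = kz_j / n_j^2 (k0 factors cancel)
  n_first <- layers[[1]]$refractive_index
  n_last <- layers[[nl]]$refractive_index
  q1 <- kz_branch(n_first, k0, kx) / n_first^2
  qN <- kz_branch(n_last, k0, kx) / n_last^2

  # accumulate the characteristic matrix of the interior layers,
  # elementwise over the angle vector
  m11 <- m22 <- complex(real = rep(1, length(kx)))
  m12 <- m21 <- complex(real = rep(0, length(kx)))
  if (nl > 2L) {
    for (j in 2:(nl - 1L)) {
      nj <- layers[[j]]$refractive_index
      dj <- layers[[j]]$thickness_nm
      kz <- kz_branch(nj, k0, kx)
      qj <- kz / nj^2
      delta <- kz * dj
      cd <- cos(delta)
      sd <- sin(delta)
      a11 <- cd
      a12 <- -1i * sd / qj
      a21 <- -1i * qj * sd
      a22 <- cd
      t11 <- m11 * a11 + m12 * a21
      t12 <- m11 * a12 + m12 * a22
      t21 <- m21 * a11 + m22 * a21
      t22 <- m21 * a12 + m22 * a22
      m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
    }
  }
  num <- (m11 + m12 * qN) * q1 - (m21 + m22 * qN)
  den <- (m11 + m12 * qN) * q1 + (m21 + m22 * qN)
  r <- num / den
  pmin(pmax(Mod(r)^2, 0), 1)
}

#' Sample the reflectance curve on an angle grid
#'
#' @param stack A [sensor_stack()].
#' @param angle_min,angle_max Grid limits in degrees; `angle_min < angle_max`.
#' @param step Grid spacing in degrees; > 0.
#' @return An object of class `angular_scan`: a data frame with columns
#'   `angle_deg` and `reflectance`.
#' @export
angular_scan <- function(stack, angle_min = 55, angle_max = 78,
                         step = 0.005) {
  check_number(step, "step", lower = 0, allow_zero_lower = FALSE)
  check_flag(angle_min < angle_max, "angle_min must be < angle_max")
  angles <- seq(angle_min, angle_max, by = step)
  check_flag(length(angles) >= 1L, "empty angle grid")
  out <- data.frame(angle_deg = angles,
                    reflectance = reflectance_p(stack, angles))
  class(out) <- c("angular_scan", class(out))
  out
}

#' Locate the SPR dip in an angular scan
#'
#' Finds the interior local minimum of the reflectance curve and refines it
#' by parabolic interpolation through the minimum sample and its two
#' neighbours.  Grid ties are broken toward the lower angle.
#'
#' @param scan An `angular_scan` (or any data frame with `angle_deg` and
#'   `reflectance` columns).
#' @return Dip angle in degrees.
#' @export
find_dip <- function(scan) {
  check_flag(is.data.frame(scan) &&
               all(c("angle_deg", "reflectance") %in% names(scan)) &&
               nrow(scan) >= 3L,
             "scan must have angle_deg and reflectance columns, >= 3 rows")
  refl <- scan$reflectance
  ang <- scan$angle_deg
  i <- which.min(refl)  # which.min takes the first (lowest-angle) tie
  if (i == 1L || i == length(refl)) {
    stop_sprcoat("reflectance minimum lies on the scan boundary; ",
                 "widen the angle range", class = "sprcoat_dip_error")
  }
  y0 <- refl[i - 1L]; y1 <- refl[i]; y2 <- refl[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom <= 0) return(ang[i])  # flat triple: no curvature to refine
  ang[i] + 0.5 * (y0 - y2) / denom * (ang[i + 1L] - ang[i])
}

#' An adsorbed homogeneous layer
#'
#' @param refractive_index Real refractive index of the adlayer.
#' @param thickness_nm Thickness in nanometres; >= 0.
#' @return An object of class `adlayer`.
#' @export
adlayer <- function(refractive_index, thickness_nm) {
  check_number(refractive_index, "refractive_index", lower = 0,
               allow_zero_lower = FALSE)
  check_number(thickness_nm, "thickness_nm", lower = 0)
  structure(list(refractive_index = refractive_index,
                 thickness_nm = thickness_nm),
            class = "adlayer")
}

#' Insert an adlayer under the ambient half-space
#'
#' @param stack A [sensor_stack()].
#' @param layer An [adlayer()].
#' @return A new `sensor_stack` with the adlayer between the outermost solid
#'   layer and the ambient medium.
#' @export
with_adlayer <- function(stack, layer) {
  check_flag(inherits(stack, "sensor_stack"), "stack must be a sensor_stack")
  check_flag(inherits(layer, "adlayer"), "layer must be an adlayer")
  nl <- length(stack$layers)
  ad <- optical_layer("adlayer", layer$refractive_index, layer$thickness_nm)
  sensor_stack(append(stack$layers, list(ad), after = nl - 1L),
               wavelength_nm = stack$wavelength_nm)
}

#' Angular response (dip shift) of an adsorbed layer
#'
#' The SPR angular response is the resonance-dip angle of the stack carrying
#' the adlayer minus the dip angle of the bare stack.  A zero-thickness
#' adlayer, or one index-matched to the ambient buffer, gives exactly zero.
#'
#' @param stack A [sensor_stack()].
#' @param layer An [adlayer()].
#' @param angle_min,angle_max,step Scan grid passed to [angular_scan()].
#' @return Dip shift in degrees (>= 0 when the adlayer index exceeds the
#'   ambient index).
#' @export
#' @examples
#' \donttest{
#' angular_response(bcg_sensor_stack(), adlayer(1.35, 351.1))  # ~2.28 deg
#' }
angular_response <- function(stack, layer, angle_min = 55, angle_max = 78,
                             step = 0.005) {
  check_flag(inherits(layer, "adlayer"), "layer must be an adlayer")
  n_ambient <- stack$layers[[length(stack$layers)]]$refractive_index
  if (layer$thickness_nm == 0 ||
      (Im(n_ambient) == 0 && layer$refractive_index == Re(n_ambient))) {
    return(0)
  }
  bare <- find_dip(angular_scan(stack, angle_min, angle_max, step))
  coated <- find_dip(angular_scan(with_adlayer(stack, layer),
                                  angle_min, angle_max, step))
  coated - bare
}

#' Maximum angular response of a full particle monolayer
#'
#' Combines the geometry and optics models: a full hexagonally packed
#' monolayer of particles is represented as a homogeneous slab with the
#' particle's refractive index and the effective thickness from
#' [effective_layer_thickness()], and its dip shift is computed.  This value
#' is the denominator that turns a measured immobilization response into a
#' surface-coverage fraction.
#'
#' @param stack A [sensor_stack()].
#' @param particle A [particle_model()].
#' @param ... Scan-grid arguments passed on to [angular_response()].
#' @return Maximum monolayer response in degrees.
#' @export
max_monolayer_response <- function(stack, particle, ...) {
  check_flag(inherits(particle, "particle_model"),
             "particle must be a particle_model")
  angular_response(stack,
                   adlayer(particle$refractive_index,
                           particle$effective_thickness_nm),
                   ...)
}
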