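# Independent oracles and random-case generators.
#
# parratt_reflectance_p() is a from-scratch recursive-Fresnel (Parratt)
# implementation of p-polarized multilayer reflectance.  It shares no code
# with the package's characteristic-matrix path and serves as its oracle.

parratt_reflectance_p <- function(stack, angle_deg) {
  layers <- stack$layers
  n <- vapply(layers, function(l) l$refractive_index, complex(1))
  d <- vapply(layers, function(l) l$thickness_nm, numeric(1))
  k0 <- 2 * pi / stack$wavelength_nm
  N <- length(n)
  vapply(angle_deg, function(a) {
    kx <- k0 * Re(n[1]) * sin(a * pi / 180)
    kz <- sqrt((k0 * n)^2 - kx^2 + 0i)
    flip <- Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0)
    kz[flip] <- -kz[flip]
    X <- 0 + 0i
    for (j in (N - 1):1) {
      rj <- (n[j + 1]^2 * kz[j] - n[j]^2 * kz[j + 1]) /
            (n[j + 1]^2 * kz[j] + n[j]^2 * kz[j + 1])
      phase <- if (j + 1 < N) exp(2i * kz[j + 1] * d[j + 1]) else 1 + 0i
      X <- (rj + X * phase) / (1 + rj * X * phase)
    }
    Mod(X)^2
  }, numeric(1))
}

# random lossless dielectric stack with n_interior interior layers
random_dielectric_stack <- function(n_interior) {
  mk <- function(i, thick = NA_real_) {
    optical_layer(paste0("L", i), stats::runif(1, 1.2, 2.5), thick)
  }
  layers <- c(list(mk(0)),
              lapply(seq_len(n_interior),
                     function(i) mk(i, stats::runif(1, 10, 300))),
              list(mk(n_interior + 1)))
  sensor_stack(layers, wavelength_nm = stats::runif(1, 500, 900))
}

# random stack that may include absorbing (metal-like) layers
random_absorbing_stack <- function(n_interior) {
  mk_n <- function() {
    if (stats::runif(1) < 0.4) {
      complex(real = stats::runif(1, 0.1, 3),
              imaginary = stats::runif(1, 0, 4))
    } else {
      stats::runif(1, 1.2, 2.5)
    }
  }
  layers <- c(list(optical_layer("top", stats::runif(1, 1.4, 1.7))),
              lapply(seq_len(n_interior), function(i) {
                optical_layer(paste0("L", i), mk_n(),
                              stats::runif(1, 5, 200))
              }),
              list(optical_layer("bottom", mk_n())))
  sensor_stack(layers, wavelength_nm = stats::runif(1, 500, 900))
}

bcg_paper_inputs <- function() {
  list(
    coverages = c(`6K-AH1` = 0.226, `6K-TRP2` = 0.136,
                  `CPP-SIINFEKL` = 0.110),
    mass_per_area = c(`6K-AH1` = 35.3, `6K-TRP2` = 301.6,
                      `CPP-SIINFEKL` = 163.0),
    mw = c(`6K-AH1` = 1868.21, `6K-TRP2` = 1944.4,
           `CPP-SIINFEKL` = 3279.9),
    printed_particles = c(`6K-AH1` = 275269, `6K-TRP2` = 165397,
                          `CPP-SIINFEKL` = 133729),
    printed_mass_ng = c(`6K-AH1` = 0.277, `6K-TRP2` = 2.369,
                        `CPP-SIINFEKL` = 1.280),
    printed_molecules = c(`6K-AH1` = 8.9e10, `6K-TRP2` = 7.3e11,
                          `CPP-SIINFEKL` = 2.4e11),
    printed_per_particle = c(`6K-AH1` = 3.2e5, `6K-TRP2` = 4.4e6,
                             `CPP-SIINFEKL` = 1.8e6)
  )
}

run_config_fixture <- function() {
  system.file("extdata", "bcg_run.json", package = "sprcoat")
}
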