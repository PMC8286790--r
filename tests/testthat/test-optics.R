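test_that("reflectance limits: no interface and total internal reflection", {
  same <- sensor_stack(list(optical_layer("a", 1.5),
                            optical_layer("b", 1.5)))
  expect_equal(reflectance_p(same, c(10, 45, 80)), c(0, 0, 0))

  tir <- sensor_stack(list(optical_layer("prism", 1.515),
                           optical_layer("water", 1.335)))
  critical <- asin(1.335 / 1.515) * 180 / pi  # ~61.8 deg
  expect_equal(reflectance_p(tir, critical + c(0.5, 5, 15)), c(1, 1, 1),
               tolerance = 1e-12)
  expect_lt(reflectance_p(tir, critical - 5), 1)
})

test_that("transfer-matrix reflectance matches the Parratt oracle", {
  withr::with_seed(101, {
    for (rep in 1:8) {
      stack <- random_dielectric_stack(sample(1:4, 1))
      angles <- sort(stats::runif(10, 5, 85))
      expect_equal(reflectance_p(stack, angles),
                   parratt_reflectance_p(stack, angles),
                   tolerance = 1e-10)
    }
    # absorbing stacks (metal layers) up to 6 layers total
    for (rep in 1:8) {
      stack <- random_absorbing_stack(sample(1:4, 1))
      angles <- sort(stats::runif(10, 5, 85))
      expect_equal(reflectance_p(stack, angles),
                   parratt_reflectance_p(stack, angles),
                   tolerance = 1e-10)
    }
  })
})

test_that("reflectance stays in [0, 1] for randomized non-gain stacks", {
  withr::with_seed(202, {
    for (rep in 1:10) {
      stack <- random_absorbing_stack(sample(1:4, 1))
      r <- reflectance_p(stack, seq(1, 89, by = 2))
      expect_true(all(r >= 0 & r <= 1))
    }
  })
})

test_that("angular_scan samples the grid and the sensor shows one dip", {
  stack <- bcg_sensor_stack()
  tiny <- angular_scan(stack, 60, 61, 0.5)
  expect_s3_class(tiny, "angular_scan")
  expect_equal(tiny$angle_deg, c(60, 60.5, 61))

  scan <- angular_scan(stack, 55, 78, 0.01)
  refl <- scan$reflectance
  interior_minima <- which(diff(sign(diff(refl))) > 0) + 1L
  expect_length(interior_minima, 1L)   # a single SPR dip
  expect_lt(min(refl), 0.15)           # deep resonance
  expect_error(angular_scan(stack, 70, 60, 0.01), "angle_min")
})

test_that("find_dip refines with a parabola and rejects boundary minima", {
  expect_equal(find_dip(data.frame(angle_deg = c(60, 61, 62),
                                   reflectance = c(1.0, 0.2, 1.0))), 61.0)
  # closed-form parabola vertex: 61 + 0.5*(0.9-0.3)/(0.9-0.4+0.3) = 61.375
  expect_equal(find_dip(data.frame(angle_deg = c(60, 61, 62),
                                   reflectance = c(0.9, 0.2, 0.3))), 61.375)
  expect_error(find_dip(data.frame(angle_deg = 60:64,
                                   reflectance = c(5, 4, 3, 2, 1) / 5)),
               "boundary")
})

test_that("angular response zero cases are exactly zero", {
  stack <- bcg_sensor_stack()
  expect_identical(angular_response(stack, adlayer(1.42, 0)), 0)
  expect_identical(angular_response(stack, adlayer(1.335, 250)), 0)
  zero_index_particle <- particle_model(refractive_index = 1.335)
  expect_identical(max_monolayer_response(stack, zero_index_particle), 0)
})

test_that("thin adlayers respond linearly in thickness x index contrast", {
  stack <- bcg_sensor_stack()
  cases <- expand.grid(d = c(1, 3, 5), n = c(1.365, 1.395))
  resp <- mapply(function(d, n) angular_response(stack, adlayer(n, d)),
                 cases$d, cases$n)
  slope <- resp / (cases$d * (cases$n - 1.335))
  expect_lt(max(abs(slope / mean(slope) - 1)), 0.05)
})

test_that("adlayer response saturates: non-decreasing toward an asymptote", {
  stack <- bcg_sensor_stack()
  thick <- c(0, 25, 50, 100, 200, 350, 500, 700)
  resp <- vapply(thick,
                 function(d) angular_response(stack, adlayer(1.35, d)),
                 numeric(1))
  expect_true(all(diff(resp) >= 0))
  # late increments are small relative to early ones (approach to asymptote)
  expect_lt(resp[8] - resp[7], 0.05 * (resp[2] - resp[1]) * 8)
  # halved diameter gives strictly smaller monolayer response
  full <- max_monolayer_response(stack, particle_model())
  half_d_vol <- 0.3887 / 8  # halving diameter divides volume by 8
  expect_lt(max_monolayer_response(stack, particle_model(half_d_vol)), full)
})

test_that("the calibrated stack reproduces the reference monolayer shift", {
  stack <- bcg_sensor_stack()
  resp <- angular_response(stack, adlayer(1.35, 351.1))
  expect_equal(round(resp, 2), 2.28)
  expect_equal(max_monolayer_response(stack, particle_model()), resp,
               tolerance = 1e-3)
})

test_that("stack validation and file round-trip", {
  expect_error(optical_layer("x", -1.5), "refractive_index")
  expect_error(sensor_stack(list(optical_layer("a", 1.5))), "layers")
  expect_error(
    sensor_stack(list(optical_layer("a", 1.5),
                      optical_layer("m", 1.2, 50),
                      optical_layer("b", 1.33, 10))),
    "half-space")

  fixture <- system.file("extdata", "bcg_sensor.json", package = "sprcoat")
  stack <- read_sensor_stack(fixture)
  expect_equal(reflectance_p(stack, c(60, 68, 74)),
               reflectance_p(bcg_sensor_stack(), c(60, 68, 74)))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_sensor_stack(stack, tmp)
  stack2 <- read_sensor_stack(tmp)
  expect_equal(stack2, stack)
})
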