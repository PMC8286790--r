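default_schedule <- function() {
  injection_schedule(start_s = 60, association_s = 720,
                     dissociation_s = 180, concentration_M = 1e-4)
}
default_params <- function() langmuir_parameters(1e4, 1e-3, 0.6)

test_that("sensorgram construction enforces a strictly increasing clock", {
  s <- sensorgram(0:9, rep(0.5, 10))
  expect_length(s$time_s, 10)
  err <- expect_error(sensorgram(c(0, 1, 1, 2), 1:4),
                      class = "sprcoat_format_error")
  expect_match(conditionMessage(err), "row 3")
})

test_that("sensorgram files round-trip at full precision", {
  sched <- default_schedule()
  s <- simulate_sensorgram(default_params(), sched, noise_sd = 0.01,
                           seed = 7, bulk_shift_deg = 0.05)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sensorgram(s, tmp)
  s2 <- read_sensorgram(tmp)
  expect_identical(s2$time_s, s$time_s)
  expect_identical(s2$response_deg, s$response_deg)
  expect_identical(s2$channel, s$channel)
  expect_equal(s2$metadata[names(s$metadata)], s$metadata)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tresponse_deg\tchannel",
               "0\t0.1\ta", "2\t0.2\ta", "1\t0.3\ta"), bad)
  err <- expect_error(read_sensorgram(bad), class = "sprcoat_format_error")
  expect_match(conditionMessage(err), "row 4|row 3")

  nocol <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tvalue", "0\t0.1"), nocol)
  expect_error(read_sensorgram(nocol), "response_deg")
})

test_that("reference subtraction removes bulk shift and common drift", {
  sched <- default_schedule()
  p <- default_params()
  active <- simulate_sensorgram(p, sched, bulk_shift_deg = 0.08,
                                drift_deg_per_s = 1e-5)
  reference <- simulate_sensorgram(langmuir_parameters(0, 0, 0), sched,
                                   bulk_shift_deg = 0.08,
                                   drift_deg_per_s = 1e-5,
                                   channel = "reference")
  corrected <- reference_subtract(active, reference)
  pure <- langmuir_response(active$time_s, p, sched)
  expect_equal(corrected$response_deg, pure, tolerance = 1e-12)

  # zero reference leaves active unchanged; self-subtraction gives zeros
  zero_ref <- sensorgram(active$time_s, rep(0, length(active$time_s)),
                         "reference")
  expect_equal(reference_subtract(active, zero_ref)$response_deg,
               active$response_deg)
  expect_equal(reference_subtract(active, active)$response_deg,
               rep(0, length(active$time_s)))

  # interpolation path: reference on a coarser grid covering the active one
  coarse <- sensorgram(seq(0, 960, by = 3),
                       approx(reference$time_s, reference$response_deg,
                              seq(0, 960, by = 3))$y, "reference")
  corr2 <- reference_subtract(active, coarse)
  # linear interpolation smears the bulk-shift step; compare away from the
  # two flow-switch edges
  away <- abs(active$time_s - 60) > 3 & abs(active$time_s - 780) > 3
  expect_equal(corr2$response_deg[away], pure[away], tolerance = 1e-6)

  late <- sensorgram(active$time_s + 2000, active$response_deg)
  expect_error(reference_subtract(active, late),
               class = "sprcoat_format_error")
})

test_that("steady_state_response averages the window and reports spread", {
  s <- sensorgram(0:100, rep(0.42, 101))
  v <- steady_state_response(s, c(10, 20))
  expect_equal(as.numeric(v), 0.42)
  expect_equal(attr(v, "sd"), 0)
  expect_equal(attr(v, "n"), 11L)

  ramp <- sensorgram(0:100, seq(0, 1, length.out = 101))
  expect_equal(as.numeric(steady_state_response(ramp, c(40, 60))), 0.5)
  expect_error(steady_state_response(s, c(90, 200)),
               class = "sprcoat_window_error")
})

test_that("simulated kinetics follow the closed form and its limits", {
  sched <- default_schedule()
  p <- default_params()
  s <- simulate_sensorgram(p, sched, noise_sd = 0)
  expect_equal(s$response_deg, langmuir_response(s$time_s, p, sched),
               tolerance = 1e-12)

  # saturating concentration, no dissociation: plateau at R_max
  sat <- injection_schedule(start_s = 0, association_s = 5000,
                            dissociation_s = 10, concentration_M = 1e-2)
  irrev <- langmuir_parameters(1e4, 0, 0.6)
  plateau <- steady_state_response(
    simulate_sensorgram(irrev, sat), c(4000, 5000))
  expect_equal(as.numeric(plateau), 0.6, tolerance = 1e-3)

  # R_eq = R_max * konC/(konC + koff) = 0.6 / 1.001 for the defaults
  long <- injection_schedule(start_s = 0, association_s = 20000,
                             dissociation_s = 10, concentration_M = 1e-4)
  pl <- steady_state_response(simulate_sensorgram(p, long, dt = 10),
                              c(15000, 20000))
  expect_equal(as.numeric(pl), 0.6 / 1.001, tolerance = 1e-4)

  # bounded and phase-monotone without noise
  expect_true(all(s$response_deg >= 0 & s$response_deg <= p$R_max))
  assoc <- s$time_s >= 60 & s$time_s <= 780
  expect_true(all(diff(s$response_deg[assoc]) >= 0))
  expect_true(all(diff(s$response_deg[s$time_s > 780]) <= 0))

  # seeded noise is reproducible and does not advance the global RNG
  set.seed(99); before <- rnorm(1); set.seed(99)
  a <- simulate_sensorgram(p, sched, noise_sd = 0.01, seed = 5)
  b <- simulate_sensorgram(p, sched, noise_sd = 0.01, seed = 5)
  expect_identical(a$response_deg, b$response_deg)
  expect_identical(rnorm(1), before)
  expect_error(simulate_sensorgram(p, sched, noise_sd = -1), "noise_sd")
})

test_that("fit_langmuir recovers noiseless parameters to 0.1%", {
  sched <- default_schedule()
  p <- default_params()
  s <- simulate_sensorgram(p, sched, noise_sd = 0)
  est <- fit_langmuir(s, sched)
  expect_equal(est$k_on, p$k_on, tolerance = 1e-3)
  expect_equal(est$k_off, p$k_off, tolerance = 1e-3)
  expect_equal(est$R_max, p$R_max, tolerance = 1e-3)
  expect_false(attr(est, "low_signal"))
})

test_that("fit_langmuir parameter recovery at 2% noise over 20 seeds", {
  sched <- default_schedule()
  p <- default_params()
  rel_err <- t(vapply(1:20, function(seed) {
    s <- simulate_sensorgram(p, sched, noise_sd = 0.02 * p$R_max,
                             seed = seed)
    est <- fit_langmuir(s, sched)
    abs(c(est$k_on / p$k_on, est$k_off / p$k_off,
          est$R_max / p$R_max) - 1)
  }, numeric(3)))
  med <- apply(rel_err, 2, stats::median)
  expect_lt(med[1], 0.05)  # k_on
  expect_lt(med[2], 0.05)  # k_off
  expect_lt(med[3], 0.05)  # R_max
})

test_that("a flat zero curve is flagged low-signal", {
  sched <- default_schedule()
  flat <- simulate_sensorgram(langmuir_parameters(0, 0, 0), sched,
                              noise_sd = 0.002, seed = 3)
  est <- fit_langmuir(flat, sched)
  expect_lt(est$R_max, 0.01)
  expect_true(attr(est, "low_signal"))
})
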