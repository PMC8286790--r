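#' SPR sensorgrams: I/O, reference correction, simulation and fitting
#'
#' A sensorgram is the time series of angular response recorded in one flow
#' channel during an injection cycle.  The binding assay runs two channels:
#' the analyte is injected over a particle-coated surface (active) and an
#' uncoated surface (reference); the pointwise difference isolates specific
#' binding from bulk refractive-index shifts and drift.  Synthetic
#' sensorgrams follow the Langmuir 1:1 interaction model
#' `dR/dt = k_on C (R_max - R) - k_off R`.
#'
#' @name sensorgram
NULL

#' Construct a sensorgram
#'
#' @param time_s Time points in seconds, strictly increasing.
#' @param response_deg Angular response in degrees, same length.
#' @param channel Channel label (e.g. `"active"`, `"reference"`).
#' @param metadata Named list of run metadata (flow_rate_ul_min,
#'   temperature_c, analyte, concentration_um, ...).
#' @return Object of class `sensorgram`.
#' @export
sensorgram <- function(time_s, response_deg, channel = "active",
                       metadata = list()) {
  check_flag(is.numeric(time_s) && is.numeric(response_deg) &&
               length(time_s) == length(response_deg) &&
               length(time_s) >= 1L,
             "time_s and response_deg must be equal-length numeric vectors")
  bad <- which(diff(time_s) <= 0)
  if (length(bad)) {
    stop_sprcoat("time must be strictly increasing; first violation at row ",
                 bad[1] + 1L, " (t = ", time_s[bad[1] + 1L], " s)",
                 class = "sprcoat_format_error")
  }
  structure(list(time_s = as.numeric(time_s),
                 response_deg = as.numeric(response_deg),
                 channel = as.character(channel),
                 metadata = metadata),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram [%s]: %d samples, t = %.1f..%.1f s, R = %.4f..%.4f deg\n",
              x$channel, length(x$time_s), min(x$time_s), max(x$time_s),
              min(x$response_deg), max(x$response_deg)))
  invisible(x)
}

#' Read and write sensorgram files
#'
#' Plain tab-delimited text with `#`-prefixed `key: value` metadata header
#' lines followed by a header row `time_s  response_deg  channel`.  Writing
#' then reading restores the series at full double precision.
#'
#' @param path File path.
#' @return `read_sensorgram()` returns a [sensorgram()];
#'   `write_sensorgram()` returns `path` invisibly.
#' @export
read_sensorgram <- function(path) {
  check_flag(file.exists(path), "sensorgram file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      metadata[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("time_s", "response_deg", "channel"), names(df))
  if (length(missing)) {
    stop_sprcoat("sensorgram file lacks column(s): ",
                 paste(missing, collapse = ", "),
                 class = "sprcoat_format_error")
  }
  channel <- unique(df$channel)
  check_flag(length(channel) == 1L,
             "sensorgram file must contain a single channel")
  sensorgram(df$time_s, df$response_deg, channel, metadata)
}

#' @param s A [sensorgram()] to serialize.
#' @rdname read_sensorgram
#' @export
write_sensorgram <- function(s, path) {
  check_flag(inherits(s, "sensorgram"), "s must be a sensorgram")
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(s$metadata)) {
    writeLines(sprintf("# %s: %s", key, format(s$metadata[[key]],
                                               digits = 17)), con)
  }
  writeLines("time_s\tresponse_deg\tchannel", con)
  writeLines(sprintf("%.17g\t%.17g\t%s", s$time_s, s$response_deg,
                     s$channel), con)
  invisible(path)
}

#' Reference-channel subtraction
#'
#' Subtracts the uncoated-channel response from the active-channel response,
#' removing bulk refractive-index shifts and common-mode drift.  If the time
#' grids differ, the reference is linearly interpolated onto the active
#' grid; the active grid must lie within the reference time range.
#'
#' @param active Sensorgram over the particle-coated surface.
#' @param reference Sensorgram over the uncoated surface.
#' @return A [sensorgram()] on the active grid, channel
#'   `"<active>-corrected"`, metadata inherited from `active`.
#' @export
reference_subtract <- function(active, reference) {
  check_flag(inherits(active, "sensorgram") &&
               inherits(reference, "sensorgram"),
             "active and reference must be sensorgrams")
  if (length(active$time_s) == length(reference$time_s) &&
      all(active$time_s == reference$time_s)) {
    ref_resp <- reference$response_deg
  } else {
    if (min(active$time_s) < min(reference$time_s) ||
        max(active$time_s) > max(reference$time_s)) {
      stop_sprcoat("active time range [", min(active$time_s), ", ",
                   max(active$time_s),
                   "] s extends beyond the reference range; cannot ",
                   "interpolate", class = "sprcoat_format_error")
    }
    ref_resp <- stats::approx(reference$time_s, reference$response_deg,
                              xout = active$time_s)$y
  }
  sensorgram(active$time_s, active$response_deg - ref_resp,
             channel = paste0(active$channel, "-corrected"),
             metadata = active$metadata)
}

#' Steady-state (plateau) response over a time window
#'
#' @param s A [sensorgram()].
#' @param window Numeric `c(t0, t1)` in seconds, inside the series range and
#'   covering at least 3 samples.
#' @return Mean response over the window (degrees), with attributes `sd`
#'   (within-window standard deviation) and `n` (samples used).
#' @export
steady_state_response <- function(s, window) {
  check_flag(inherits(s, "sensorgram"), "s must be a sensorgram")
  check_flag(is.numeric(window) && length(window) == 2L &&
               window[1] < window[2], "window must be c(t0, t1), t0 < t1")
  if (window[1] < min(s$time_s) || window[2] > max(s$time_s)) {
    stop_sprcoat("window [", window[1], ", ", window[2],
                 "] s lies outside the sensorgram time range",
                 class = "sprcoat_window_error")
  }
  sel <- s$time_s >= window[1] & s$time_s <= window[2]
  check_flag(sum(sel) >= 3L, "window must contain at least 3 samples")
  vals <- s$response_deg[sel]
  structure(mean(vals), sd = stats::sd(vals), n = sum(sel))
}

#' Injection schedule
#'
#' @param start_s Injection start time, seconds.
#' @param association_s Association (analyte flow) duration; default 720 s
#'   (12 min injection).
#' @param dissociation_s Dissociation (buffer wash) duration; default 180 s
#'   (3 min wash).
#' @param concentration_M Analyte molar concentration; default 1e-4
#'   (100 uM).
#' @return Object of class `injection_schedule`.
#' @export
injection_schedule <- function(start_s = 60, association_s = 720,
                               dissociation_s = 180,
                               concentration_M = 1e-4) {
  check_number(start_s, "start_s", lower = 0)
  check_number(association_s, "association_s", lower = 0,
               allow_zero_lower = FALSE)
  check_number(dissociation_s, "dissociation_s", lower = 0,
               allow_zero_lower = FALSE)
  check_number(concentration_M, "concentration_M", lower = 0)
  structure(list(start_s = start_s, association_s = association_s,
                 dissociation_s = dissociation_s,
                 concentration_M = concentration_M),
            class = "injection_schedule")
}

#' Langmuir 1:1 interaction parameters
#'
#' @param k_on Association rate constant, 1/(M s).
#' @param k_off Dissociation rate constant, 1/s.
#' @param R_max Saturation response, degrees.
#' @return Object of class `langmuir_parameters`.
#' @export
langmuir_parameters <- function(k_on, k_off, R_max) {
  check_number(k_on, "k_on", lower = 0)
  check_number(k_off, "k_off", lower = 0)
  check_number(R_max, "R_max", lower = 0)
  structure(list(k_on = k_on, k_off = k_off, R_max = R_max),
            class = "langmuir_parameters")
}

#' Closed-form Langmuir 1:1 response
#'
#' Association: `R(t) = R_eq (1 - exp(-(k_on C + k_off) t))` with
#' `R_eq = R_max k_on C / (k_on C + k_off)`; dissociation:
#' exponential decay from the association endpoint at rate `k_off`.
#' Zero before the injection starts.
#'
#' @param time_s Time points, seconds.
#' @param params [langmuir_parameters()].
#' @param schedule [injection_schedule()].
#' @return Response in degrees at each time point.
#' @export
langmuir_response <- function(time_s, params, schedule) {
  check_flag(inherits(params, "langmuir_parameters"),
             "params must be langmuir_parameters")
  check_flag(inherits(schedule, "injection_schedule"),
             "schedule must be an injection_schedule")
  C <- schedule$concentration_M
  kobs <- params$k_on * C + params$k_off
  R_eq <- if (kobs > 0) params$R_max * params$k_on * C / kobs else 0
  t0 <- schedule$start_s
  t1 <- t0 + schedule$association_s
  r <- numeric(length(time_s))
  assoc <- time_s >= t0 & time_s <= t1
  r[assoc] <- R_eq * (1 - exp(-kobs * (time_s[assoc] - t0)))
  dissoc <- time_s > t1
  R_end <- R_eq * (1 - exp(-kobs * schedule$association_s))
  r[dissoc] <- R_end * exp(-params$k_off * (time_s[dissoc] - t1))
  r
}

#' Simulate a noisy sensorgram
#'
#' Closed-form Langmuir 1:1 kinetics plus, optionally, a bulk
#' refractive-index step while the analyte flows, a linear baseline drift,
#' and additive i.i.d. Gaussian noise.  Deterministic under a fixed seed:
#' the RNG state is restored on exit.
#'
#' @param params [langmuir_parameters()].
#' @param schedule [injection_schedule()].
#' @param noise_sd Noise standard deviation, degrees; >= 0.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param dt Sampling interval, seconds.
#' @param bulk_shift_deg Bulk response step present only while the analyte
#'   is flowing (association phase); models the refractive-index mismatch
#'   between sample and running buffer.
#' @param drift_deg_per_s Linear baseline drift rate.
#' @param channel Channel label.
#' @return A [sensorgram()] spanning baseline, association and dissociation.
#' @export
simulate_sensorgram <- function(params, schedule, noise_sd = 0, seed = NULL,
                                dt = 1, bulk_shift_deg = 0,
                                drift_deg_per_s = 0, channel = "active") {
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(dt, "dt", lower = 0, allow_zero_lower = FALSE)
  t_end <- schedule$start_s + schedule$association_s + schedule$dissociation_s
  time_s <- seq(0, t_end, by = dt)
  r <- langmuir_response(time_s, params, schedule)
  in_flow <- time_s >= schedule$start_s &
    time_s <= schedule$start_s + schedule$association_s
  r <- r + bulk_shift_deg * in_flow + drift_deg_per_s * time_s
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    r <- r + stats::rnorm(length(r), sd = noise_sd)
  }
  sensorgram(time_s, r, channel = channel,
             metadata = list(analyte = "simulated",
                             concentration_um = schedule$concentration_M * 1e6,
                             flow_rate_ul_min = 20, temperature_c = 20))
}

#' Fit the Langmuir 1:1 model to a single-cycle sensorgram
#'
#' Least-squares fit of `k_on`, `k_off` and `R_max` against the closed-form
#' association/dissociation phases, on log scale for the rate constants.
#' Starting values come from the curve itself (tail decay for `k_off`,
#' plateau for `R_eq`); Nelder-Mead is followed by a BFGS polish.
#'
#' @param s A [sensorgram()] containing one association/dissociation cycle
#'   (reference-corrected, drift-free).
#' @param schedule The [injection_schedule()] used.
#' @return [langmuir_parameters()] with attributes `residual_norm` (root
#'   mean squared residual), `convergence` (optim code, 0 = success) and
#'   `low_signal` (TRUE when the fitted amplitude is indistinguishable from
#'   the residual noise).
#' @export
fit_langmuir <- function(s, schedule) {
  check_flag(inherits(s, "sensorgram"), "s must be a sensorgram")
  check_flag(inherits(schedule, "injection_schedule"),
             "schedule must be an injection_schedule")
  C <- schedule$concentration_M
  check_flag(C > 0, "analyte concentration must be > 0 to fit")
  tt <- s$time_s
  rr <- s$response_deg

  r_peak <- max(rr)
  # start values: peak for R_eq; tail decay for k_off
  t1 <- schedule$start_s + schedule$association_s
  tail_sel <- tt > t1
  k_off0 <- 1e-3
  if (sum(tail_sel) >= 5 && r_peak > 0) {
    ry <- rr[tail_sel]
    pos <- ry > 0.05 * r_peak
    if (sum(pos) >= 5) {
      fitln <- stats::lm(log(ry[pos]) ~ tt[tail_sel][pos])
      sl <- -unname(stats::coef(fitln)[2])
      if (is.finite(sl) && sl > 1e-8) k_off0 <- sl
    }
  }
  k_on0 <- max(1 / C * 3 / max(schedule$association_s, 1), 10)
  theta0 <- c(log(k_on0), log(k_off0),
              max(r_peak, .Machine$double.eps))

  obj <- function(theta) {
    p <- langmuir_parameters(exp(theta[1]), exp(theta[2]),
                             max(theta[3], 0))
    sum((rr - langmuir_response(tt, p, schedule))^2)
  }
  fit <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (!is.finite(fit$value)) {
    stop_sprcoat("Langmuir fit failed to converge; best objective ",
                 format(fit$value), " at k_on = ", format(exp(fit$par[1])),
                 class = "sprcoat_fit_error")
  }
  est <- langmuir_parameters(exp(fit$par[1]), exp(fit$par[2]),
                             max(fit$par[3], 0))
  rmse <- sqrt(fit$value / length(rr))
  structure(est,
            residual_norm = rmse,
            convergence = fit$convergence,
            low_signal = est$R_max < 3 * rmse)
}
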