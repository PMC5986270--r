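bp <- BoltzmannParams(1.6, 0.4, 7.0, 0.5)

test_that("generators are pure functions of their seed", {
  a <- gen_calibration_trace(bp, seed = 42)
  b <- gen_calibration_trace(bp, seed = 42)
  expect_identical(a$trace$y, b$trace$y)
  expect_false(identical(a$trace$y, gen_calibration_trace(bp, seed = 43)$trace$y))

  l1 <- gen_lactate_experiment(seed = 7)
  l2 <- gen_lactate_experiment(seed = 7)
  expect_identical(l1$trace$y, l2$trace$y)

  i1 <- gen_isotope_series(seed = 5)
  i2 <- gen_isotope_series(seed = 5)
  expect_identical(i1$series$a49, i2$series$a49)

  n1 <- gen_nuclei_image(n_nuclei = 15, seed = 8)
  n2 <- gen_nuclei_image(n_nuclei = 15, seed = 8)
  expect_identical(n1$image$pixels, n2$image$pixels)
  expect_identical(n1$truth$centers, n2$truth$centers)
})

test_that("calibration staircase converges to the sigmoid value per step", {
  sim <- gen_calibration_trace(bp, step_duration_s = 300, tau_s = 20,
                               noise_sd = 0, seed = 1)
  w <- sim$truth$step_windows
  amp <- abs(bp$A1 - bp$A2)
  for (i in seq_len(nrow(w))) {
    target <- boltzmann_ratio(w$pH[i], bp)
    last <- sim$trace$y[max(which(sim$trace$t < w$end[i]))]
    expect_lt(abs(last - target), amp * exp(-295 / 20) + 1e-12)
  }
})

test_that("staircase -> steady states -> Boltzmann fit recovers the truth", {
  sim <- gen_calibration_trace(bp, noise_sd = 0.01, seed = 42)
  w <- sim$truth$step_windows
  pts <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
    seg <- segment_trace(sim$trace,
                         ApplicationProtocol(data.frame(
                           solute = "calibration", concentration = 0,
                           start = w$start[i], end = w$end[i] - 0.1)), 1)
    data.frame(pH = w$pH[i], value = as.numeric(steady_state_value(seg)))
  }))
  fit <- fit_boltzmann(pts)
  for (nm in c("A1", "A2", "x0", "dx"))
    expect_lt(abs(fit[[nm]] - bp[[nm]]) / abs(bp[[nm]]), 0.05)
})

test_that("lactate generator obeys Michaelis-Menten and buffering scaling", {
  # measured initial slope at c = K_m is half the saturating slope
  mk_prot <- function(c) ApplicationProtocol(data.frame(
    solute = "lactate", concentration = c, start = 100, end = 400))
  slope0 <- function(sim) {
    i <- which(sim$trace$t >= 100)[1]
    (sim$trace$y[i + 1] - sim$trace$y[i]) /
      (sim$trace$t[i + 1] - sim$trace$t[i])
  }
  s_km <- slope0(gen_lactate_experiment(mk_prot(5), K_m = 5, noise_sd = 0,
                                        sample_hz = 20, duration_s = 500))
  s_sat <- slope0(gen_lactate_experiment(mk_prot(5e4), K_m = 5, noise_sd = 0,
                                         sample_hz = 20, duration_s = 500))
  expect_equal(s_km / s_sat, 0.5, tolerance = 0.01)

  # doubling beta halves the initial slope at fixed J
  s_b20 <- slope0(gen_lactate_experiment(mk_prot(10), beta_true = 20,
                                         noise_sd = 0, sample_hz = 20,
                                         duration_s = 500))
  s_b40 <- slope0(gen_lactate_experiment(mk_prot(10), beta_true = 40,
                                         noise_sd = 0, sample_hz = 20,
                                         duration_s = 500))
  expect_equal(s_b20 / s_b40, 2, tolerance = 0.01)
})

test_that("the CO2-pulse steady state encodes the generating buffer strength", {
  sol <- SolutionSpec()
  sim <- gen_lactate_experiment(noise_sd = 0, seed = 1, solution = sol)
  ev <- sim$truth$events
  co2 <- ev[grepl("co2", ev$solute, ignore.case = TRUE), ]
  # closed-buffer relation: HCO3-(pH_end) = beta * (pH_start - pH_end),
  # where pH_start is the actual pre-pulse level (the trace has not fully
  # returned to baseline when the pulse starts)
  pre_pulse <- sim$trace$y[max(which(sim$trace$t < co2$start))]
  lhs <- hco3_intracellular(co2$co2_target_pH, sol)
  rhs <- sim$truth$beta_true * (pre_pulse - co2$co2_target_pH)
  expect_equal(lhs, rhs, tolerance = 1e-3)
})

test_that("electrode generator composes exactly with voltage_to_ph", {
  sim <- gen_electrode_recording(drift_mV_per_min = 0, noise_sd = 0, seed = 3)
  cal <- ElectrodeCalibration(sim$truth$electrode$slope,
                              sim$truth$electrode$intercept)
  ph <- voltage_to_ph(sim$trace, cal)
  t0 <- sim$truth$measurement_start_s
  meas <- ph$y[ph$t >= t0]
  expect_equal(meas, sim$truth$ph_trace$y, tolerance = 1e-12)
  # the prepended calibration plateaus sit at pH 7.0 and 6.4
  expect_equal(unique(ph$y[ph$t < 60]), 7.0, tolerance = 1e-12)
  expect_equal(unique(ph$y[ph$t >= 60 & ph$t < t0]), 6.4, tolerance = 1e-12)
  # two-point calibration from the plateau potentials recovers the line
  v1 <- mean(sim$trace$y[sim$trace$t < 60])
  v2 <- mean(sim$trace$y[sim$trace$t >= 60 & sim$trace$t < t0])
  cal2 <- calibrate_electrode(calibration_points(c(7.0, 6.4), c(v1, v2)))
  expect_equal(cal2$slope, cal$slope, tolerance = 1e-9)
  expect_equal(cal2$intercept, cal$intercept, tolerance = 1e-9)
})

test_that("electrode drift biases extracted rates by exactly slope*drift", {
  drift <- 0.5  # mV/min
  sim0 <- gen_electrode_recording(drift_mV_per_min = 0, noise_sd = 0, seed = 4)
  simd <- gen_electrode_recording(drift_mV_per_min = drift, noise_sd = 0,
                                  seed = 4)
  cal <- ElectrodeCalibration(sim0$truth$electrode$slope,
                              sim0$truth$electrode$intercept)
  t0 <- sim0$truth$measurement_start_s
  seg <- function(sim) {
    ph <- voltage_to_ph(sim$trace, cal)
    # 30 s fixed window at the first lactate application (t = 300 on the
    # measurement clock)
    idx <- ph$t >= t0 + 300 & ph$t <= t0 + 330
    Trace(ph$t[idx], ph$y[idx], kind = "pH")
  }
  r0 <- extract_rate(seg(sim0), mode = "fixed-window", window_s = 30)
  rd <- extract_rate(seg(simd), mode = "fixed-window", window_s = 30)
  bias <- rd$slope - r0$slope
  expect_equal(bias, cal$slope * drift, tolerance = 1e-9)
  expect_lte(abs(bias), abs(cal$slope * drift) + 1e-9)
})

test_that("nuclei generator placement matches its ground-truth record", {
  expect_equal(max(gen_nuclei_image(n_nuclei = 0, seed = 1)$image$pixels), 0)

  sim <- gen_nuclei_image(n_nuclei = 20, overlap_fraction = 0.3, seed = 12)
  tr <- sim$truth
  expect_equal(nrow(tr$centers), 20L)
  expect_equal(nrow(tr$pairs), 3L)  # round(20 * 0.3) = 6 nuclei in 3 pairs
  # independent connected-component oracle on the planted geometry
  n <- nrow(tr$centers)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((tr$centers[i, ] - tr$centers[j, ])^2))
    if (d < tr$radii[i] + tr$radii[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comps <- length(unique(vapply(seq_len(n), find, integer(1))))
  expect_equal(comps, tr$n_components)
  expect_equal(comps, 17L)
  # and the pixel-level component count agrees with the planted geometry
  plain <- max(segment_nuclei(sim$image, split_touching = FALSE))
  expect_equal(plain, comps)
})

test_that("infeasible nuclei density raises a placement error", {
  expect_error(gen_nuclei_image(n_nuclei = 500, radius_px = 20,
                                image_shape = c(100, 100), seed = 1,
                                max_tries = 50),
               class = "protonflux_placement_error")
})

test_that("ground truth serialises to JSON", {
  sim <- gen_isotope_series(U_true = 2, seed = 3, duration_s = 60,
                            addition_time_s = 30)
  p <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(back$U_true, 2)
  expect_equal(back$theta_cat, sim$truth$theta_cat)
})
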