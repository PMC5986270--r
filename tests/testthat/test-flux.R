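test_that("ph_to_proton converts and is a bijection", {
  tr <- Trace(0:3, c(7, 6.5, 6, 7.4), kind = "pH")
  h <- ph_to_proton(tr)
  expect_equal(h$y[1], 100)
  expect_equal(h$y[3], 1000)
  expect_equal(h$kind, "proton_nM")
  # strictly decreasing pH => strictly increasing [H+]
  dec <- Trace(0:10, seq(7.4, 6.4, length.out = 11), kind = "pH")
  expect_true(all(diff(ph_to_proton(dec)$y) > 0))
  # round trip to 1e-12
  expect_equal(proton_to_ph(ph_to_proton(tr))$y, tr$y, tolerance = 1e-12)
})

test_that("extract_rate recovers an exact linear slope in both modes", {
  t <- 0:120
  seg <- Trace(t, 7.3 - 0.01 * t, kind = "pH")
  for (mode in c("max-slope", "fixed-window")) {
    r <- extract_rate(seg, mode = mode, window_s = 30)
    expect_equal(r$slope, -0.6, tolerance = 1e-12)
    expect_equal(r$r2, 1)
    expect_equal(r$units, "pH/min")
  }
  # constant segment: zero slope, r2 defined as 0
  flat <- extract_rate(Trace(t, rep(7, 121), kind = "pH"), window_s = 30)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  expect_error(extract_rate(Trace(0:10, rnorm(11), kind = "pH"),
                            window_s = 60),
               class = "protonflux_window_error")
})

test_that("max-slope mode equals the exhaustive window-scan oracle", {
  # mono-exponential response, 1 Hz, 30 s window
  t <- 0:300
  y <- 7.3 - 0.3 * (1 - exp(-t / 60))
  segs <- list(
    Trace(t, y, kind = "pH"),
    Trace(t, y + withr::with_seed(21, rnorm(301, sd = 0.005)), kind = "pH"),
    # irregular sampling
    withr::with_seed(22, {
      ti <- sort(sample(t, 180))
      Trace(ti, 7.3 - 0.3 * (1 - exp(-ti / 60)) + rnorm(180, sd = 0.003),
            kind = "pH")
    }),
    # rising (withdrawal-like) phase
    Trace(t, 6.9 + 0.25 * (1 - exp(-t / 45)), kind = "pH"))
  for (seg in segs) {
    est <- extract_rate(seg, mode = "max-slope", window_s = 30)
    orc <- oracle_max_slope(seg$t, seg$y, 30)
    expect_equal(est$window, orc$window)
    expect_equal(est$slope, orc$slope * 60, tolerance = 1e-9)
  }
})

test_that("hco3_intracellular follows Henderson-Hasselbalch", {
  sol <- SolutionSpec(pco2_fraction = 0.05, hco3_mM = 10, pH_o = 7.0,
                      pK_prime = 6.1)
  # at pH_i = pK' the bicarbonate equals the dissolved CO2
  co2 <- 10 / 10^(7.0 - 6.1)
  expect_equal(hco3_intracellular(6.1, sol), co2)
  # at pH_i = pH_o the intra- and extracellular bicarbonate match
  expect_equal(hco3_intracellular(7.0, sol), 10)
  # direct arithmetic example
  expect_equal(hco3_intracellular(7.2, sol), 10 * 10^(7.2 - 7.0),
               tolerance = 1e-12)
})

test_that("buffer_capacity recovers the definition and guards tiny dpH", {
  sol <- SolutionSpec()
  # constructed pulse: plateau 7.2, acidified plateau such that dHCO3 = 10
  ph_end <- 6.7   # dpH = 0.5
  t <- 0:600
  y <- ifelse(t < 300, 7.2, ph_end + (7.2 - ph_end) * exp(-(t - 300) / 30))
  res <- buffer_capacity(Trace(t, y, kind = "pH"), sol, pulse_start_s = 300)
  expect_equal(res$pH_start, 7.2, tolerance = 1e-6)
  expect_equal(res$pH_end, ph_end, tolerance = 1e-4)
  expect_equal(res$beta_i, hco3_intracellular(ph_end, sol) / 0.5,
               tolerance = 1e-3)
  # definitional check: dpH 0.5 with 10 mM of bicarbonate formed -> 20 mM/pH
  expect_equal(res$delta_hco3 / abs(res$delta_pH),
               res$beta_i, tolerance = 1e-12)

  flat <- Trace(0:600, rep(7.2, 601), kind = "pH")
  expect_error(buffer_capacity(flat, sol, pulse_start_s = 300),
               class = "protonflux_unresolvable_buffering")
})

test_that("buffer_capacity inverts the generator's closed-form pulse", {
  sol <- SolutionSpec()
  prot <- ApplicationProtocol(data.frame(solute = "CO2", concentration = 5,
                                         start = 300, end = 700))
  sim <- gen_lactate_experiment(prot, beta_true = 20, tau_s = 30,
                                noise_sd = 0.005, seed = 17, sample_hz = 2,
                                solution = sol, duration_s = 700)
  res <- buffer_capacity(sim$trace, sol, pulse_start_s = 300)
  expect_lt(abs(res$beta_i - 20) / 20, 0.05)
})

test_that("proton_flux multiplies rate and buffering and keeps direction", {
  seg <- Trace(0:60, 7.3 - (0.01 / 60) * (0:60), kind = "pH")
  rate <- extract_rate(seg, window_s = 30, direction = "application")
  buf <- structure(list(beta_i = 20, delta_pH = -0.5, delta_hco3 = 10,
                        pH_start = 7.2, pH_end = 6.7),
                   class = "BufferingResult")
  fl <- proton_flux(rate, buf)
  expect_equal(fl$J_H, abs(rate$slope) * 20)
  expect_equal(fl$J_H, 0.01 * 20, tolerance = 1e-9)
  expect_equal(fl$direction, "application")
  # zero slope annihilates
  flat <- extract_rate(Trace(0:60, rep(7, 61), kind = "pH"), window_s = 30)
  expect_equal(proton_flux(flat, buf)$J_H, 0)
  # invariant J_H = |rate| * beta on arbitrary constructions
  for (s in c(-0.05, 0.002, 0.3)) {
    r <- rate; r$slope <- s
    expect_identical(proton_flux(r, buf)$J_H, abs(s) * buf$beta_i)
  }
  # proton-scale rates are refused
  h_rate <- extract_rate(ph_to_proton(seg), window_s = 30)
  expect_error(proton_flux(h_rate, buf), class = "protonflux_type_error")
})

test_that("injection_concentration reproduces the oocyte worked example", {
  conc <- injection_concentration(27.6, 400, 0.35)
  expect_equal(conc, 27.6e-3 * 400 / (0.35 + 27.6e-3), tolerance = 1e-12)
  expect_equal(signif(conc, 1), 30)
  # fixed point: resident concentration c injected into cell at c
  c0 <- 30
  mix <- (0.35 * c0 + 27.6e-3 * c0) / (0.35 + 27.6e-3)
  expect_equal(mix, c0)
  # null injection
  expect_equal(injection_concentration(0, 400, 0.35), 0)
  expect_error(injection_concentration(10, 400, 0),
               class = "protonflux_validation_error")
})
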