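# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed and returns both the dataset and an
# ExperimentGroundTruth recording the generating parameters, so recovery
# tests always compare against recorded truth rather than hard-coded
# numbers.

ground_truth <- function(...) {
  structure(list(...), class = "ExperimentGroundTruth")
}

#' @export
print.ExperimentGroundTruth <- function(x, ...) {
  cat("<ExperimentGroundTruth>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth An `ExperimentGroundTruth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  if (!inherits(truth, "ExperimentGroundTruth"))
    pf_stop("type_error", "write_ground_truth() expects an ExperimentGroundTruth")
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Simulate a nigericin calibration staircase
#'
#' Emulates the calibration of a ratiometric pH dye: the cell is clamped to
#' a staircase of known pH values (nigericin/high-K+), and at each step the
#' recorded ratio approaches the sigmoid value [boltzmann_ratio()] of that
#' pH mono-exponentially with time constant `tau_s` (dye/cell
#' equilibration), with additive i.i.d. Gaussian noise.
#'
#' @param params True [BoltzmannParams] of the dye.
#' @param ph_steps pH values of the staircase (>= 2 steps; default the
#'   five-step pH 6.0-8.0 staircase).
#' @param step_duration_s Duration of each step, seconds.
#' @param tau_s Equilibration time constant, seconds.
#' @param noise_sd Gaussian noise SD on the ratio.
#' @param seed RNG seed.
#' @param sample_hz Sampling rate (default the 0.4 Hz frame rate of
#'   confocal ratio imaging).
#' @return A list with `trace` (a ratio [Trace]) and `truth` (an
#'   `ExperimentGroundTruth` including per-step windows).
#' @export
gen_calibration_trace <- function(params,
                                  ph_steps = c(6.0, 6.5, 7.0, 7.5, 8.0),
                                  step_duration_s = 300, tau_s = 20,
                                  noise_sd = 0.01, seed = 1,
                                  sample_hz = 0.4) {
  if (!inherits(params, "BoltzmannParams"))
    pf_stop("type_error", "gen_calibration_trace() expects BoltzmannParams")
  if (length(ph_steps) < 2L)
    pf_stop("validation_error", "need at least 2 calibration steps")
  n_steps <- length(ph_steps)
  targets <- boltzmann_ratio(ph_steps, params)
  t <- seq(0, n_steps * step_duration_s - 1 / sample_hz, by = 1 / sample_hz)
  step_of <- pmin(floor(t / step_duration_s) + 1, n_steps)
  y <- numeric(length(t))
  level <- targets[1L]  # already equilibrated at the first step
  for (k in seq_len(n_steps)) {
    idx <- step_of == k
    tl <- t[idx] - (k - 1) * step_duration_s
    y[idx] <- targets[k] + (level - targets[k]) * exp(-tl / tau_s)
    level <- targets[k] + (level - targets[k]) * exp(-step_duration_s / tau_s)
  }
  y <- with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  windows <- data.frame(pH = ph_steps,
                        start = (seq_len(n_steps) - 1) * step_duration_s,
                        end = seq_len(n_steps) * step_duration_s)
  list(trace = Trace(t, y, kind = "ratio", meta = list(simulated = TRUE)),
       truth = ground_truth(boltzmann = unclass(params), ph_steps = ph_steps,
                            step_duration_s = step_duration_s, tau_s = tau_s,
                            noise_sd = noise_sd, sample_hz = sample_hz,
                            step_windows = windows, seed = seed))
}

# Piecewise mono-exponential pH trajectory driven by an event protocol.
# During a substrate event of concentration c the initial slope is
# -(J_max * c / (c + K_m)) / beta (Michaelis-Menten influx over buffering),
# relaxing with time constant tau toward the quasi-steady pH; after the
# event the pH relaxes back toward baseline. A CO2/HCO3- event acidifies
# toward the pH at which the Henderson-Hasselbalch bicarbonate load equals
# beta times the pH displacement, i.e. the steady state a closed buffer of
# strength beta would show.
ph_trajectory <- function(t, events, J_max, K_m, beta, tau_s, baseline_pH,
                          solution) {
  y <- rep(baseline_pH, length(t))
  if (!nrow(events)) return(y)
  ev <- events[order(events$start), , drop = FALSE]
  if (nrow(ev) > 1L && any(ev$start[-1L] < ev$end[-nrow(ev)]))
    pf_stop("validation_error",
            "the pH-trajectory generator needs strictly sequential events")
  level <- baseline_pH
  co2_targets <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$start[i]; t1 <- ev$end[i]
    if (is_co2_event(ev$solute[i])) {
      target <- stats::uniroot(
        function(x) hco3_intracellular(x, solution) - beta * (level - x),
        lower = 3, upper = level - 1e-9, tol = 1e-12)$root
      co2_targets[i] <- target
    } else {
      s0 <- (J_max * ev$concentration[i] / (ev$concentration[i] + K_m)) /
        beta / 60  # pH units per second, magnitude
      target <- level - s0 * tau_s
    }
    idx <- t >= t0 & t < t1
    y[idx] <- target + (level - target) * exp(-(t[idx] - t0) / tau_s)
    level <- target + (level - target) * exp(-(t1 - t0) / tau_s)
    post_hi <- if (i < nrow(ev)) ev$start[i + 1L] else Inf
    idx <- t >= t1 & t < post_hi
    y[idx] <- baseline_pH + (level - baseline_pH) * exp(-(t[idx] - t1) / tau_s)
    if (is.finite(post_hi))
      level <- baseline_pH + (level - baseline_pH) * exp(-(post_hi - t1) / tau_s)
  }
  attr(y, "co2_targets") <- co2_targets
  y
}

default_lactate_protocol <- function() {
  ApplicationProtocol(data.frame(
    solute = c("lactate", "lactate", "CO2"),
    concentration = c(3, 10, 5),
    start = c(300, 900, 1500),
    end = c(600, 1200, 1800)))
}

#' Simulate a lactate-pulse pH recording with known proton fluxes
#'
#' Emulates the intracellular pH response of a cell expressing a
#' monocarboxylate transporter to lactate application and withdrawal: during
#' application of concentration `c` the initial acidification rate is
#' `-(J_max * c / (c + K_m)) / beta_true` (Michaelis-Menten influx divided
#' by buffering), relaxing mono-exponentially with time constant `tau_s`;
#' withdrawal mirrors the response back toward baseline. A terminal
#' CO2/HCO3- pulse acidifies to the steady state consistent with
#' `beta_true`, so that [buffer_capacity()] and [proton_flux()] can recover
#' the generating flux. Gaussian noise is added on the pH scale.
#'
#' @param protocol An [ApplicationProtocol]; the default applies 3 and
#'   10 mM lactate followed by a 5% CO2 / 10 mM HCO3- pulse.
#' @param J_max Maximal transport flux, mM/min.
#' @param K_m Michaelis constant of the transporter, mM (about 5 mM
#'   lactate for MCT1).
#' @param beta_true Intrinsic buffer capacity, mM per pH unit.
#' @param tau_s Response time constant, seconds.
#' @param baseline_pH Resting intracellular pH.
#' @param noise_sd Gaussian noise SD, pH units.
#' @param seed RNG seed.
#' @param sample_hz Sampling rate, Hz.
#' @param solution [SolutionSpec] of the CO2 pulse.
#' @param duration_s Total record length (default: last event end + 300 s).
#' @return A list with `trace` (a pH [Trace]) and `truth` including the
#'   per-event true fluxes `J_true` (mM/min) and initial slopes
#'   (pH/min), `beta_true`, and the CO2-pulse steady-state pH.
#' @export
gen_lactate_experiment <- function(protocol = default_lactate_protocol(),
                                   J_max = 3, K_m = 5, beta_true = 20,
                                   tau_s = 60, baseline_pH = 7.2,
                                   noise_sd = 0.005, seed = 1,
                                   sample_hz = 1,
                                   solution = SolutionSpec(),
                                   duration_s = NULL) {
  if (!inherits(protocol, "ApplicationProtocol"))
    pf_stop("type_error", "gen_lactate_experiment() expects an ApplicationProtocol")
  ev <- protocol$events
  duration_s <- duration_s %||% (max(ev$end) + 300)
  t <- seq(0, duration_s, by = 1 / sample_hz)
  y <- ph_trajectory(t, ev, J_max, K_m, beta_true, tau_s, baseline_pH,
                     solution)
  co2_targets <- attr(y, "co2_targets")
  yn <- with_seed(seed, as.numeric(y) + stats::rnorm(length(y), sd = noise_sd))
  lact <- !is_co2_event(ev$solute)
  J_true <- ifelse(lact, J_max * ev$concentration / (ev$concentration + K_m),
                   NA_real_)
  truth <- ground_truth(
    events = cbind(ev, J_true = J_true,
                   s0_pH_per_min = ifelse(lact, -J_true / beta_true, NA_real_),
                   co2_target_pH = co2_targets),
    J_max = J_max, K_m = K_m, beta_true = beta_true, tau_s = tau_s,
    baseline_pH = baseline_pH, noise_sd = noise_sd, sample_hz = sample_hz,
    solution = unclass(solution), seed = seed)
  list(trace = Trace(t, yn, kind = "pH", meta = list(simulated = TRUE)),
       truth = truth)
}

#' Simulate an ion-sensitive electrode recording
#'
#' Maps a known pH trajectory (same kinetic model as
#' [gen_lactate_experiment()]) through the inverse of the electrode line
#' `pH = intercept + slope * V_e`, adds linear electrode drift and Gaussian
#' noise in mV, and prepends the two-solution calibration segments (pH 7.0
#' and pH 6.4) recorded before each experiment. Protocol event times are on
#' the measurement clock, which starts after the two calibration segments.
#'
#' @inheritParams gen_lactate_experiment
#' @param slope,intercept True electrode line (pH per mV; pH units).
#' @param drift_mV_per_min Linear electrode drift.
#' @param noise_sd Gaussian noise SD, mV.
#' @param cal_duration_s Duration of each calibration segment, seconds.
#' @param cal_ph The two calibration pH values.
#' @return A list with `trace` (a potential [Trace] covering calibration +
#'   measurement) and `truth` including the underlying pH trace
#'   (`ph_trace`), the electrode line, the calibration windows and the
#'   measurement start time.
#' @export
gen_electrode_recording <- function(protocol = default_lactate_protocol(),
                                    J_max = 3, K_m = 5, beta_true = 20,
                                    tau_s = 60, baseline_pH = 7.2,
                                    slope = -0.02, intercept = 7.0,
                                    drift_mV_per_min = 0, noise_sd = 0,
                                    seed = 1, sample_hz = 2,
                                    solution = SolutionSpec(),
                                    duration_s = NULL,
                                    cal_duration_s = 60,
                                    cal_ph = c(7.0, 6.4)) {
  if (slope == 0)
    pf_stop("validation_error", "electrode `slope` must be nonzero")
  sim <- gen_lactate_experiment(protocol = protocol, J_max = J_max,
                                K_m = K_m, beta_true = beta_true,
                                tau_s = tau_s, baseline_pH = baseline_pH,
                                noise_sd = 0, seed = seed,
                                sample_hz = sample_hz, solution = solution,
                                duration_s = duration_s)
  meas_start <- 2 * cal_duration_s
  dt <- 1 / sample_hz
  t_cal <- seq(0, meas_start - dt, by = dt)
  ph_cal <- ifelse(t_cal < cal_duration_s, cal_ph[1L], cal_ph[2L])
  t_all <- c(t_cal, sim$trace$t + meas_start)
  ph_all <- c(ph_cal, sim$trace$y)
  v <- (ph_all - intercept) / slope +
    drift_mV_per_min * t_all / 60
  v <- with_seed(seed + 1L, v + stats::rnorm(length(v), sd = noise_sd))
  cal_windows <- data.frame(pH = cal_ph,
                            start = c(0, cal_duration_s),
                            end = c(cal_duration_s, meas_start))
  truth <- ground_truth(
    electrode = list(slope = slope, intercept = intercept),
    drift_mV_per_min = drift_mV_per_min, noise_sd = noise_sd,
    cal_windows = cal_windows, measurement_start_s = meas_start,
    kinetics = unclass(sim$truth), seed = seed)
  truth$ph_trace <- sim$trace
  list(trace = Trace(t_all, v, kind = "potential_mV",
                     meta = list(simulated = TRUE)),
       truth = truth)
}

# Closed-form first-order 18O-depletion cascade:
#   d a49/dt = -2 theta a49
#   d a47/dt = 2 theta a49 - theta a47
#   d a45/dt = theta a47
# Total abundance is conserved; a45 is obtained by difference.
cascade_state <- function(state, theta, t) {
  e1 <- exp(-theta * t); e2 <- exp(-2 * theta * t)
  a49 <- state[["a49"]] * e2
  a47 <- state[["a47"]] * e1 + 2 * state[["a49"]] * (e1 - e2)
  total <- state[["a45"]] + state[["a47"]] + state[["a49"]]
  cbind(a45 = total - a49 - a47, a47 = a47, a49 = a49)
}

#' Simulate an 18O isotope-exchange recording
#'
#' Deterministic first-order depletion cascade across m/z 49 -> 47 -> 45
#' with per-18O-atom exchange rate `theta_uncat` before lysate addition and
#' `theta_uncat * (1 + U_true)` after it (by the unit definition, an
#' activity of `U_true` units stimulates the uncatalyzed depletion by
#' `U_true * 100` percent). Optional Poisson counting noise at the scale of
#' the initial total abundance. In the noiseless record the log enrichment
#' is exactly linear with slope `-2 theta / ln(10)` per second in each
#' phase.
#'
#' @param theta_uncat Uncatalyzed per-atom exchange rate, 1/s.
#' @param U_true True enzyme activity, units (>= 0).
#' @param addition_time_s Lysate addition time, seconds.
#' @param duration_s Record length, seconds.
#' @param counts_scale Initial total abundance (ion counts).
#' @param noise Add Poisson counting noise.
#' @param seed RNG seed.
#' @param sample_hz Sampling rate, Hz.
#' @param init_fracs Initial isotopologue fractions (named `a49`, `a47`,
#'   `a45`; mostly doubly labelled at the start of an assay).
#' @return A list with `series` (an [IsotopeSeries]) and `truth` including
#'   the true LE slopes (per minute) of both phases.
#' @export
gen_isotope_series <- function(theta_uncat = 1e-3, U_true = 5,
                               addition_time_s = 300, duration_s = 900,
                               counts_scale = 1e4, noise = TRUE, seed = 1,
                               sample_hz = 1,
                               init_fracs = c(a49 = 0.95, a47 = 0.04,
                                              a45 = 0.01)) {
  stopifnot_number(theta_uncat, "theta_uncat")
  stopifnot_number(U_true, "U_true")
  if (U_true < 0) pf_stop("validation_error", "`U_true` must be >= 0")
  if (addition_time_s <= 0 || addition_time_s >= duration_s)
    pf_stop("validation_error",
            "`addition_time_s` must lie strictly inside the record")
  theta_cat <- theta_uncat * (1 + U_true)
  t <- seq(0, duration_s, by = 1 / sample_hz)
  state0 <- counts_scale * init_fracs[c("a45", "a47", "a49")] /
    sum(init_fracs)
  pre <- t <= addition_time_s
  ab <- matrix(NA_real_, length(t), 3,
               dimnames = list(NULL, c("a45", "a47", "a49")))
  ab[pre, ] <- cascade_state(state0, theta_uncat, t[pre])
  state_add <- cascade_state(state0, theta_uncat, addition_time_s)[1L, ]
  ab[!pre, ] <- cascade_state(state_add, theta_cat, t[!pre] - addition_time_s)
  if (noise)
    ab <- with_seed(seed, matrix(stats::rpois(length(ab), lambda = ab),
                                 nrow(ab), dimnames = dimnames(ab)))
  le_slope <- function(th) -2 * th * 60 / log(10)
  truth <- ground_truth(theta_uncat = theta_uncat, theta_cat = theta_cat,
                        U_true = U_true, addition_time_s = addition_time_s,
                        counts_scale = counts_scale, noise = noise,
                        sample_hz = sample_hz,
                        le_slope_uncat_per_min = le_slope(theta_uncat),
                        le_slope_cat_per_min = le_slope(theta_cat),
                        seed = seed)
  list(series = IsotopeSeries(t, ab[, "a45"], ab[, "a47"], ab[, "a49"]),
       truth = truth)
}

#' Simulate a nuclei image with known ground truth
#'
#' Places disk-shaped nuclei (Gaussian radius jitter) on a black background:
#' a requested fraction of the nuclei form touching pairs (centre distance
#' 0.75 times the sum of radii, i.e. clearly fused but watershed-separable),
#' the rest are placed with rejection sampling so that no two non-pair disks
#' touch. Nuclei carry Gaussian texture noise around the stated intensity;
#' all centres, radii and pairings are recorded.
#'
#' @param n_nuclei Number of nuclei to plant (>= 0).
#' @param radius_px Mean nucleus radius, pixels.
#' @param radius_sd_px SD of the radius jitter, pixels.
#' @param overlap_fraction Fraction of nuclei belonging to a touching pair,
#'   in `[0, 1)`.
#' @param intensity Nucleus intensity (8-bit scale).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size, micrometres (default 0.65, a 10x
#'   objective on a typical camera).
#' @param texture_sd SD of the within-nucleus intensity texture.
#' @param seed RNG seed.
#' @param max_tries Placement attempts per nucleus before giving up with a
#'   placement error.
#' @return A list with `image` (a [NucleiImage]) and `truth` including
#'   `centers` (x = row, y = col), `radii`, `pairs` and the expected number
#'   of connected components `n_components`.
#' @export
gen_nuclei_image <- function(n_nuclei = 100, radius_px = 10,
                             radius_sd_px = 1, overlap_fraction = 0,
                             intensity = 200, image_shape = c(512, 512),
                             pixel_size_um = 0.65, texture_sd = 10,
                             seed = 1, max_tries = 2000) {
  stopifnot_number(n_nuclei, "n_nuclei")
  if (n_nuclei < 0) pf_stop("validation_error", "`n_nuclei` must be >= 0")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    pf_stop("validation_error", "`overlap_fraction` must be in [0, 1)")
  nr <- image_shape[1L]; nc <- image_shape[2L]
  with_seed(seed, {
    px <- matrix(0, nr, nc)
    centers <- matrix(numeric(), 0, 2)
    radii <- numeric()
    pairs <- matrix(integer(), 0, 2)
    if (n_nuclei > 0) {
      n_touch <- round(n_nuclei * overlap_fraction)
      if (n_touch %% 2L == 1L) n_touch <- n_touch - 1L
      n_pairs <- n_touch %/% 2L
      draw_radius <- function() max(3, stats::rnorm(1, radius_px, radius_sd_px))
      sep_ok <- function(cx, cy, r, skip = integer()) {
        if (!nrow(centers)) return(TRUE)
        keep <- setdiff(seq_len(nrow(centers)), skip)
        if (!length(keep)) return(TRUE)
        d <- sqrt((centers[keep, 1L] - cx)^2 + (centers[keep, 2L] - cy)^2)
        all(d > radii[keep] + r + 2)
      }
      place <- function(r, near = NULL, near_r = NULL) {
        for (k in seq_len(max_tries)) {
          if (is.null(near)) {
            cx <- stats::runif(1, r + 2, nr - r - 1)
            cy <- stats::runif(1, r + 2, nc - r - 1)
            if (sep_ok(cx, cy, r)) return(c(cx, cy))
          } else {
            ang <- stats::runif(1, 0, 2 * pi)
            d <- 0.75 * (r + near_r)
            cx <- near[1L] + d * cos(ang); cy <- near[2L] + d * sin(ang)
            if (cx > r + 1 && cx < nr - r && cy > r + 1 && cy < nc - r &&
                sep_ok(cx, cy, r, skip = nrow(centers)))
              return(c(cx, cy))
          }
        }
        pf_stop("placement_error",
                sprintf("could not place nucleus %d after %d tries; density too high",
                        nrow(centers) + 1L, max_tries))
      }
      for (p in seq_len(n_pairs)) {
        r1 <- draw_radius(); c1 <- place(r1)
        centers <- rbind(centers, c1); radii <- c(radii, r1)
        r2 <- draw_radius(); c2 <- place(r2, near = c1, near_r = r1)
        centers <- rbind(centers, c2); radii <- c(radii, r2)
        pairs <- rbind(pairs, c(nrow(centers) - 1L, nrow(centers)))
      }
      for (s in seq_len(n_nuclei - 2L * n_pairs)) {
        r1 <- draw_radius(); c1 <- place(r1)
        centers <- rbind(centers, c1); radii <- c(radii, r1)
      }
      for (i in seq_len(nrow(centers))) {
        r <- radii[i]; cx <- centers[i, 1L]; cy <- centers[i, 2L]
        xs <- max(1, floor(cx - r)):min(nr, ceiling(cx + r))
        ys <- max(1, floor(cy - r)):min(nc, ceiling(cy + r))
        sub <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
        vals <- intensity + stats::rnorm(sum(sub), sd = texture_sd)
        block <- px[xs, ys, drop = FALSE]
        block[sub] <- pmax(block[sub], vals)
        px[xs, ys] <- block
      }
      px <- round(pmin(pmax(px, 0), 255))
    }
    dimnames(centers) <- NULL
    truth <- ground_truth(n_nuclei = n_nuclei, centers = centers,
                          radii = radii, pairs = pairs,
                          n_components = n_nuclei - nrow(pairs),
                          radius_px = radius_px, radius_sd_px = radius_sd_px,
                          overlap_fraction = overlap_fraction,
                          intensity = intensity, texture_sd = texture_sd,
                          pixel_size_um = pixel_size_um, seed = seed)
    list(image = NucleiImage(px, pixel_size_um), truth = truth)
  })
}
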