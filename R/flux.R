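#' Convert a pH trace to intracellular proton concentration
#'
#' Element-wise `[H+] = 10^(-pH) * 1e9` nM. Because pH is logarithmic, the
#' proton-concentration change produced by a given pH change depends on the
#' baseline; transport rates are therefore often reported on the nM scale.
#'
#' @param trace A [Trace] of kind `"pH"`.
#' @return A [Trace] of kind `"proton_nM"`.
#' @examples
#' ph_to_proton(Trace(0:3, c(7, 7, 6, 6), kind = "pH"))$y  # 100 100 1000 1000
#' @export
ph_to_proton <- function(trace) {
  assert_kind(trace, "pH", "ph_to_proton")
  Trace(trace$t, 10^(-trace$y) * 1e9, kind = "proton_nM", meta = trace$meta)
}

#' Convert a proton-concentration trace back to pH
#'
#' Exact inverse of [ph_to_proton()]: `pH = -log10([H+] nM * 1e-9)`.
#'
#' @param trace A [Trace] of kind `"proton_nM"`.
#' @return A [Trace] of kind `"pH"`.
#' @export
proton_to_ph <- function(trace) {
  assert_kind(trace, "proton_nM", "proton_to_ph")
  Trace(trace$t, -log10(trace$y * 1e-9), kind = "pH", meta = trace$meta)
}

# Centered OLS over (t, y); returns slope per second and r^2.
# A segment with zero variance in y has slope 0 and r^2 defined as 0.
ols_slope <- function(t, y) {
  tc <- t - mean(t)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  syy <- sum(yc^2)
  if (syy == 0) return(list(slope = 0, r2 = 0))
  sxy <- sum(tc * yc)
  slope <- sxy / sxx
  list(slope = slope, r2 = sxy^2 / (sxx * syy))
}

#' Transport-rate estimate from a trace segment
#'
#' Extracts the rate of change of a pH (or proton-concentration) segment by
#' linear regression, either over a fixed window anchored at the segment
#' start (the event edge) or as the maximal-magnitude slope of a sliding
#' window -- the "maximum rate of change" readout of transport activity.
#'
#' In `max-slope` mode every window of length `window_s` starting at a
#' sample and fully contained in the segment is fitted by ordinary least
#' squares; the window with maximal `|slope|` wins, ties broken by the
#' earliest window. Irregular sampling is honoured: a window is the set of
#' samples with `t` in `[t_i, t_i + window_s]` and needs at least 3 samples.
#'
#' @param segment A [Trace] (pH, proton_nM or log_enrichment).
#' @param mode `"max-slope"` or `"fixed-window"`.
#' @param window_s Regression window length in seconds.
#' @param direction `"application"` or `"withdrawal"`; metadata describing
#'   which phase of the solution change the segment covers.
#' @return An object of class `RateEstimate`: a list with `slope` (per
#'   minute), `window` (`c(t_a, t_b)` in seconds), `direction`, `r2`,
#'   `mode`, `n` (samples in the winning window) and `units`.
#' @export
extract_rate <- function(segment, mode = c("max-slope", "fixed-window"),
                         window_s = 30,
                         direction = c("application", "withdrawal")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (!is_trace(segment))
    pf_stop("type_error", "extract_rate() expects a Trace")
  stopifnot_number(window_s, "window_s")
  if (window_s <= 0)
    pf_stop("validation_error", "`window_s` must be positive")
  t <- segment$t; y <- segment$y; n <- length(t)
  span <- t[n] - t[1L]
  eps <- 1e-9 * max(1, abs(t[n]))
  if (span + eps < window_s)
    pf_stop("window_error",
            sprintf("window (%g s) is longer than the segment (%g s)",
                    window_s, span))
  fit_window <- function(i0) {
    # t is sorted, so the window [t_i, t_i + window_s] is a contiguous run
    hi <- findInterval(t[i0] + window_s + eps, t)
    j <- i0:hi
    if (length(j) < 3L) return(NULL)
    f <- ols_slope(t[j], y[j])
    list(slope = f$slope, r2 = f$r2, window = c(t[j[1L]], t[j[length(j)]]),
         n = length(j))
  }
  if (mode == "fixed-window") {
    best <- fit_window(1L)
    if (is.null(best))
      pf_stop("insufficient_data",
              "fewer than 3 samples in the fixed window")
  } else {
    starts <- which(t + window_s <= t[n] + eps)
    best <- NULL
    for (i0 in starts) {
      f <- fit_window(i0)
      if (is.null(f)) next
      if (is.null(best) || abs(f$slope) > abs(best$slope)) best <- f
    }
    if (is.null(best))
      pf_stop("insufficient_data",
              "no admissible window with >= 3 samples found")
  }
  units <- switch(segment$kind,
                  pH = "pH/min", proton_nM = "nM/min",
                  log_enrichment = "LE/min",
                  paste0(segment$kind, "/min"))
  structure(list(slope = best$slope * 60, window = best$window,
                 direction = direction, r2 = best$r2, mode = mode,
                 n = best$n, units = units),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("<RateEstimate> %.4g %s (%s, %s) over [%g, %g] s, r2 = %.3f, n = %d\n",
              x$slope, x$units, x$direction, x$mode,
              x$window[1L], x$window[2L], x$r2, x$n))
  invisible(x)
}

#' Intracellular bicarbonate from intracellular pH
#'
#' Henderson-Hasselbalch conversion assuming CO2 equilibrates freely across
#' the membrane: the dissolved CO2 set by the superfusate,
#' `[CO2] = hco3_mM / 10^(pH_o - pK')`, combines with the intracellular pH
#' to give `[HCO3-]_i = [CO2] * 10^(pH_i - pK')`. At `pH_i = pH_o` the
#' intracellular bicarbonate equals the extracellular concentration.
#'
#' @param pH_i Intracellular pH (numeric vector).
#' @param solution A [SolutionSpec] describing the applied CO2/HCO3-
#'   solution.
#' @return Intracellular bicarbonate concentration, mM.
#' @export
hco3_intracellular <- function(pH_i, solution) {
  if (!inherits(solution, "SolutionSpec"))
    pf_stop("type_error", "hco3_intracellular() expects a SolutionSpec")
  co2 <- solution$hco3_mM / 10^(solution$pH_o - solution$pK_prime)
  co2 * 10^(pH_i - solution$pK_prime)
}

#' Intrinsic buffer capacity from a CO2/HCO3- pulse
#'
#' Determines the intrinsic (non-CO2) buffer capacity `beta_i` from the
#' acidification produced by a CO2/HCO3- pulse applied at the end of an
#' experiment. The pre-pulse pH plateau and the in-pulse steady state are
#' both extracted by exponential regression ([steady_state_value()]); the
#' bicarbonate formed during the pulse is obtained from the in-pulse pH by
#' Henderson-Hasselbalch. Because the experiment runs in the nominal absence
#' of CO2/HCO3-, the pre-pulse intracellular bicarbonate is taken as 0 mM,
#' so the bicarbonate change equals the in-pulse value, and
#' `beta_i = delta[HCO3-]_i / |delta pH_i|` (mM per pH unit).
#'
#' @param segment A [Trace] of kind `"pH"` covering the pre-pulse baseline
#'   and the CO2 pulse.
#' @param solution A [SolutionSpec] for the pulse solution.
#' @param pulse_start_s Time (seconds, on the trace's clock) at which the
#'   CO2/HCO3- solution reaches the cell.
#' @return An object of class `BufferingResult`: list with `beta_i` (mM per
#'   pH unit), `delta_pH` (pH_end - pH_start, negative for acidification),
#'   `delta_hco3` (mM), `pH_start`, `pH_end`.
#' @export
buffer_capacity <- function(segment, solution, pulse_start_s) {
  assert_kind(segment, "pH", "buffer_capacity")
  if (!inherits(solution, "SolutionSpec"))
    pf_stop("type_error", "buffer_capacity() expects a SolutionSpec")
  stopifnot_number(pulse_start_s, "pulse_start_s")
  t <- segment$t
  if (pulse_start_s <= t[1L] || pulse_start_s >= t[length(t)])
    pf_stop("window_error",
            "`pulse_start_s` must fall strictly inside the segment")
  pre <- window_trace(segment, t[1L], pulse_start_s, "buffer_capacity")
  pulse <- window_trace(segment, pulse_start_s, t[length(t)],
                        "buffer_capacity")
  if (length(pre$t) < 4L || length(pulse$t) < 4L)
    pf_stop("insufficient_data",
            "need >= 4 samples on each side of the pulse start")
  pH_start <- as.numeric(steady_state_value(pre))
  pH_end <- as.numeric(steady_state_value(pulse))
  delta_pH <- pH_end - pH_start
  if (abs(delta_pH) < 0.01)
    pf_stop("unresolvable_buffering",
            sprintf("pulse-induced pH change (%.4f) is below the 0.01 resolution guard",
                    delta_pH))
  delta_hco3 <- hco3_intracellular(pH_end, solution)  # pre-pulse [HCO3-]_i = 0
  structure(list(beta_i = delta_hco3 / abs(delta_pH),
                 delta_pH = delta_pH, delta_hco3 = delta_hco3,
                 pH_start = pH_start, pH_end = pH_end),
            class = "BufferingResult")
}

#' @export
print.BufferingResult <- function(x, ...) {
  cat(sprintf("<BufferingResult> beta_i = %.4g mM/pH (dpH = %.4g, dHCO3 = %.4g mM, pH %.3f -> %.3f)\n",
              x$beta_i, x$delta_pH, x$delta_hco3, x$pH_start, x$pH_end))
  invisible(x)
}

#' Proton flux from a pH rate and buffer capacity
#'
#' `J_H = |dpH/dt| * beta_i` in mM/min: the acid-equivalent flux across the
#' membrane that produces the observed pH rate at the measured intrinsic
#' buffer capacity. The sign of the underlying pH change is carried by the
#' rate's `direction` metadata rather than by `J_H` itself, matching how
#' influx and efflux are reported side by side.
#'
#' @param rate A [RateEstimate] in pH units per minute.
#' @param buffering A [BufferingResult].
#' @return An object of class `FluxResult`: list with `J_H` (mM/min),
#'   `rate_pH` (pH/min, signed), `beta_i` and `direction`.
#' @export
proton_flux <- function(rate, buffering) {
  if (!inherits(rate, "RateEstimate"))
    pf_stop("type_error", "proton_flux() expects a RateEstimate")
  if (!identical(rate$units, "pH/min"))
    pf_stop("type_error",
            sprintf("proton_flux() needs a rate in pH/min, got %s", rate$units))
  if (!inherits(buffering, "BufferingResult"))
    pf_stop("type_error", "proton_flux() expects a BufferingResult")
  structure(list(J_H = abs(rate$slope) * buffering$beta_i,
                 rate_pH = rate$slope, beta_i = buffering$beta_i,
                 direction = rate$direction),
            class = "FluxResult")
}

#' @export
print.FluxResult <- function(x, ...) {
  cat(sprintf("<FluxResult> J_H = %.4g mM/min (%s; rate %.4g pH/min, beta_i %.4g mM/pH)\n",
              x$J_H, x$direction, x$rate_pH, x$beta_i))
  invisible(x)
}

#' Intracellular concentration after a microinjection
#'
#' Concentration reached when `inject_volume` nl of an `inject_conc` mM
#' stock is injected into a cell of effective free volume `free_volume` ul:
#' `(V_inj * C_inj) / (V_free + V_inj)`. For an oocyte (effective free
#' volume about 0.35 ul), injecting 27.6 nl of a 400 mM stock yields about
#' 29.2 mM, i.e. 30 mM to one significant figure -- the convention used when
#' reporting such injections.
#'
#' @param inject_volume_nl Injected volume, nl (>= 0).
#' @param inject_conc_mM Stock concentration, mM (>= 0).
#' @param free_volume_ul Effective free volume of the cell, ul (> 0).
#' @return Intracellular concentration in mM (full precision; round with
#'   `signif(x, 1)` for reporting).
#' @examples
#' injection_concentration(27.6, 400, 0.35)            # 29.24 mM
#' signif(injection_concentration(27.6, 400, 0.35), 1) # 30 mM
#' @export
injection_concentration <- function(inject_volume_nl, inject_conc_mM,
                                    free_volume_ul) {
  stopifnot_number(inject_volume_nl, "inject_volume_nl")
  stopifnot_number(inject_conc_mM, "inject_conc_mM")
  stopifnot_number(free_volume_ul, "free_volume_ul")
  if (inject_volume_nl < 0)
    pf_stop("validation_error", "`inject_volume_nl` must be >= 0")
  if (inject_conc_mM < 0)
    pf_stop("validation_error", "`inject_conc_mM` must be >= 0")
  if (free_volume_ul <= 0)
    pf_stop("validation_error", "`free_volume_ul` must be positive")
  v_inj_ul <- inject_volume_nl / 1000
  (v_inj_ul * inject_conc_mM) / (free_volume_ul + v_inj_ul)
}

#' Per-event transport quantification of a pH recording
#'
#' Orchestrates the full per-cell analysis of one recording: for every
#' substrate (non-CO2) event the application and withdrawal rates are
#' extracted ([extract_rate()]); if the protocol contains a CO2/HCO3- pulse
#' the intrinsic buffer capacity is determined from it ([buffer_capacity()])
#' and every pH rate is converted to a proton flux ([proton_flux()]).
#'
#' @param trace A [Trace] of kind `"pH"` (calibrate raw traces first with
#'   [ratio_to_ph()] or [voltage_to_ph()]).
#' @param protocol An [ApplicationProtocol].
#' @param solution A [SolutionSpec] for the CO2 pulse (used only if the
#'   protocol contains one).
#' @param mode,window_s Passed to [extract_rate()].
#' @param withdrawal_span_s How far past each event end the withdrawal
#'   segment extends (clipped to the next event / trace end).
#' @param baseline_span_s Pre-pulse baseline length used for the buffer-
#'   capacity fit.
#' @return A data frame with one row per event phase: `event`, `solute`,
#'   `concentration`, `direction`, `slope` (pH/min), `r2`, `window_start`,
#'   `window_end`, `beta_i`, `J_H`.
#' @export
quantify_events <- function(trace, protocol, solution = SolutionSpec(),
                            mode = "max-slope", window_s = 30,
                            withdrawal_span_s = 180, baseline_span_s = 120) {
  assert_kind(trace, "pH", "quantify_events")
  if (!inherits(protocol, "ApplicationProtocol"))
    pf_stop("type_error", "quantify_events() expects an ApplicationProtocol")
  ev <- protocol$events
  co2_rows <- which(is_co2_event(ev$solute))
  buffering <- NULL
  if (length(co2_rows)) {
    i <- co2_rows[length(co2_rows)]
    seg <- window_trace(trace, ev$start[i] - baseline_span_s, ev$end[i],
                        "quantify_events")
    buffering <- tryCatch(buffer_capacity(seg, solution, ev$start[i]),
                          error = function(e) NULL)
  }
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (is_co2_event(ev$solute[i])) next
    app_seg <- segment_trace(trace, protocol, i, pad_s = 0)
    app <- extract_rate(app_seg, mode = mode, window_s = window_s,
                        direction = "application")
    next_start <- ev$start[ev$start > ev$end[i]]
    wd_hi <- min(c(ev$end[i] + withdrawal_span_s, next_start,
                   trace$t[length(trace$t)]))
    wd <- NULL
    if (wd_hi - ev$end[i] >= window_s) {
      wd_seg <- window_trace(trace, ev$end[i], wd_hi, "quantify_events")
      wd <- tryCatch(extract_rate(wd_seg, mode = mode, window_s = window_s,
                                  direction = "withdrawal"),
                     error = function(e) NULL)
    }
    for (r in Filter(Negate(is.null), list(app, wd))) {
      rows[[length(rows) + 1L]] <- data.frame(
        event = i, solute = ev$solute[i], concentration = ev$concentration[i],
        direction = r$direction, slope = r$slope, r2 = r$r2,
        window_start = r$window[1L], window_end = r$window[2L],
        beta_i = if (is.null(buffering)) NA_real_ else buffering$beta_i,
        J_H = if (is.null(buffering)) NA_real_ else
          proton_flux(r, buffering)$J_H)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
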