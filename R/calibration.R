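#' Boltzmann calibration parameters for a ratiometric pH dye
#'
#' Parameters of the sigmoid mapping pH to the dye emission ratio,
#' `R(pH) = (A1 - A2) / (1 + exp((pH - x0)/dx)) + A2`, as obtained from a
#' nigericin calibration: `A1` is the initial (acidic-limit) ratio, `A2` the
#' final (alkaline-limit) ratio, `x0` the centre in pH units and `dx` the
#' sigmoid width in pH units.
#'
#' @param A1,A2 Asymptotic ratio values; must differ.
#' @param x0 Sigmoid centre, pH units.
#' @param dx Sigmoid width, pH units; must be nonzero.
#' @return An object of class `BoltzmannParams`.
#' @export
BoltzmannParams <- function(A1, A2, x0, dx) {
  stopifnot_number(A1, "A1"); stopifnot_number(A2, "A2")
  stopifnot_number(x0, "x0"); stopifnot_number(dx, "dx")
  if (A1 == A2)
    pf_stop("validation_error", "`A1` and `A2` must differ (flat sigmoid)")
  if (dx == 0)
    pf_stop("validation_error", "`dx` must be nonzero")
  structure(list(A1 = A1, A2 = A2, x0 = x0, dx = dx),
            class = "BoltzmannParams")
}

#' @export
print.BoltzmannParams <- function(x, ...) {
  cat(sprintf("<BoltzmannParams> A1 = %.4g, A2 = %.4g, x0 = %.4g, dx = %.4g\n",
              x$A1, x$A2, x$x0, x$dx))
  if (!is.null(attr(x, "residual")))
    cat(sprintf("  fit: residual norm %.3g over %d point(s), converged: %s\n",
                attr(x, "residual"), attr(x, "n_points"),
                attr(x, "converged")))
  invisible(x)
}

#' Linear calibration of an ion-sensitive pH electrode
#'
#' The two-point (or least-squares) line `pH = intercept + slope * V_e`
#' relating electrode potential to pH.
#'
#' @param slope pH per mV; finite and nonzero.
#' @param intercept pH units.
#' @return An object of class `ElectrodeCalibration`.
#' @export
ElectrodeCalibration <- function(slope, intercept) {
  stopifnot_number(slope, "slope"); stopifnot_number(intercept, "intercept")
  if (slope == 0)
    pf_stop("validation_error", "electrode `slope` must be nonzero")
  structure(list(slope = slope, intercept = intercept),
            class = "ElectrodeCalibration")
}

#' @export
print.ElectrodeCalibration <- function(x, ...) {
  cat(sprintf("<ElectrodeCalibration> pH = %.4g + %.4g * V_e\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Calibration points
#'
#' One steady-state reading (ratio or electrode potential) at a known pH.
#' `calibration_points()` builds the small table consumed by
#' [fit_boltzmann()] and [calibrate_electrode()].
#'
#' @param pH Numeric vector of calibration pH values, each in `[5, 9]`.
#' @param value Numeric vector of steady-state ratios or potentials (mV).
#' @return A data frame with columns `pH` and `value`.
#' @export
calibration_points <- function(pH, value) {
  if (length(pH) != length(value))
    pf_stop("validation_error", "`pH` and `value` must have the same length")
  if (any(!is.finite(pH)) || any(!is.finite(value)))
    pf_stop("validation_error", "calibration points must be finite")
  if (any(pH < 5 | pH > 9))
    pf_stop("validation_error", "calibration pH values must lie in [5, 9]")
  data.frame(pH = as.double(pH), value = as.double(value))
}

as_calibration_points <- function(points, op) {
  if (is.data.frame(points) && all(c("pH", "value") %in% names(points)))
    return(calibration_points(points$pH, points$value))
  pf_stop("type_error",
          sprintf("%s() expects a data frame with columns `pH` and `value` (see calibration_points())", op))
}

# ---------------------------------------------------------------------------
# Steady-state extraction
# ---------------------------------------------------------------------------

#' Steady-state value of a trace segment by exponential regression
#'
#' Fits the mono-exponential `y(t) = y_ss + (y_0 - y_ss) * exp(-t/tau)` to
#' the segment (time re-zeroed to its first sample, so the result is
#' invariant under time shifts) and returns the asymptote `y_ss`. If the
#' nonlinear fit fails to converge the mean of the final quartile of samples
#' is returned instead; the method actually used is recorded in the
#' `"method"` attribute (`"exponential"`, `"final_quartile"` or
#' `"constant"`).
#'
#' @param segment A [Trace] with at least 4 samples.
#' @return The steady-state value in the segment's units, with attributes
#'   `method` and (for exponential fits) `tau` and `y0`.
#' @export
steady_state_value <- function(segment) {
  if (!is_trace(segment))
    pf_stop("type_error", "steady_state_value() expects a Trace")
  n <- length(segment$t)
  if (n < 4L)
    pf_stop("insufficient_data",
            sprintf("steady_state_value() needs >= 4 samples, got %d", n))
  ts <- segment$t - segment$t[1L]
  y <- segment$y
  span <- ts[n]
  final_quartile <- function() {
    idx <- ts >= 0.75 * span
    structure(mean(y[idx]), method = "final_quartile")
  }
  if (diff(range(y)) < 1e-12 * max(1, abs(mean(y))))
    return(structure(y[1L], method = "constant"))
  start <- list(y_ss = mean(y[ts >= 0.75 * span]), y0 = y[1L],
                tau = max(span / 5, 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y_ss + (y0 - y_ss) * exp(-ts / tau),
                      start = start,
                      lower = c(y_ss = -Inf, y0 = -Inf, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(final_quartile())
  cf <- stats::coef(fit)
  # A fitted time constant much longer than the segment itself means the
  # data cannot distinguish the exponential from linear drift, and the
  # asymptote is unconstrained extrapolation; use the plateau mean instead.
  if (cf[["tau"]] > 2 * span) return(final_quartile())
  structure(unname(cf[["y_ss"]]), method = "exponential",
            tau = unname(cf[["tau"]]), y0 = unname(cf[["y0"]]))
}

# ---------------------------------------------------------------------------
# Boltzmann fit and inversion
# ---------------------------------------------------------------------------

#' Evaluate the Boltzmann calibration sigmoid
#'
#' `R(pH) = (A1 - A2) / (1 + exp((pH - x0)/dx)) + A2`. At `pH = x0` the
#' ratio is the midpoint `(A1 + A2)/2`; the limits for very acidic and very
#' alkaline pH are `A1` and `A2` respectively.
#'
#' @param pH Numeric vector of pH values.
#' @param params A [BoltzmannParams].
#' @return Numeric vector of ratios.
#' @export
boltzmann_ratio <- function(pH, params) {
  if (!inherits(params, "BoltzmannParams"))
    pf_stop("type_error", "boltzmann_ratio() expects BoltzmannParams")
  (params$A1 - params$A2) / (1 + exp((pH - params$x0) / params$dx)) + params$A2
}

#' Convert a fluorescence ratio to pH by inverting the Boltzmann sigmoid
#'
#' The exact algebraic inverse of [boltzmann_ratio()]:
#' `pH = x0 + dx * ln((A1 - A2)/(R - A2) - 1)`. Valid only for ratios
#' strictly between the two asymptotes. Ratios grazing an asymptote within
#' `clamp_tol` (measurement noise at a saturated dye) are clamped just inside
#' the domain and reported via the `"clamped"` attribute; ratios further out
#' raise a domain error identifying the offending sample.
#'
#' @param R Numeric vector of ratios, or a [Trace] of kind `"ratio"` (in
#'   which case a [Trace] of kind `"pH"` is returned).
#' @param params A [BoltzmannParams].
#' @param clamp_tol Absolute tolerance for clamping near-boundary ratios.
#' @return pH values (numeric vector, or a pH [Trace] when `R` is a Trace).
#' @export
ratio_to_ph <- function(R, params, clamp_tol = 1e-9) {
  if (!inherits(params, "BoltzmannParams"))
    pf_stop("type_error", "ratio_to_ph() expects BoltzmannParams")
  if (is_trace(R)) {
    assert_kind(R, "ratio", "ratio_to_ph")
    v <- ratio_to_ph(R$y, params, clamp_tol = clamp_tol)
    return(Trace(R$t, as.numeric(v), kind = "pH",
                 meta = c(R$meta, list(
                   calibration = params,
                   n_clamped = length(attr(v, "clamped") %||% integer())))))
  }
  lo <- min(params$A1, params$A2)
  hi <- max(params$A1, params$A2)
  bad <- which(R <= lo - clamp_tol | R >= hi + clamp_tol)
  if (length(bad))
    pf_stop("domain_error",
            sprintf("ratio %g (sample %d) lies outside the calibration range (%g, %g)",
                    R[bad[1L]], bad[1L], lo, hi),
            samples = bad)
  clamped <- which(R <= lo | R >= hi)
  if (length(clamped)) {
    inset <- max(clamp_tol, (hi - lo) * 1e-12)
    R[R <= lo] <- lo + inset
    R[R >= hi] <- hi - inset
  }
  pH <- params$x0 + params$dx * log((params$A1 - params$A2) / (R - params$A2) - 1)
  if (length(clamped)) attr(pH, "clamped") <- clamped
  pH
}

#' Fit the Boltzmann calibration sigmoid to nigericin calibration points
#'
#' Least-squares estimation of `(A1, A2, x0, dx)` from steady-state ratios
#' recorded at known clamped pH values (typically pH 6.0, 6.5, 7.0, 7.5,
#' 8.0). Starting values are taken from the data (acid-limit ratio, alkaline-
#' limit ratio, median pH) and the fit is restarted over a small grid of
#' initial widths; the best converged solution is returned.
#'
#' @param points A data frame with columns `pH` and `value`
#'   (see [calibration_points()]); at least 4 distinct pH values spanning
#'   at least 1 pH unit.
#' @return A [BoltzmannParams] with attributes `residual` (residual norm),
#'   `converged` and `n_points`.
#' @export
fit_boltzmann <- function(points) {
  pts <- as_calibration_points(points, "fit_boltzmann")
  pts <- pts[order(pts$pH), ]
  if (length(unique(pts$pH)) < 4L)
    pf_stop("insufficient_data",
            sprintf("fit_boltzmann() needs >= 4 distinct pH values, got %d",
                    length(unique(pts$pH))))
  if (diff(range(pts$pH)) < 1)
    pf_stop("insufficient_data",
            "calibration pH values must span at least 1 pH unit")
  if (diff(range(pts$value)) < 1e-10 * max(1, abs(mean(pts$value))))
    pf_stop("unidentifiability_error",
            "calibration values are constant across pH; sigmoid parameters are unidentifiable")
  span <- diff(range(pts$pH))
  best <- NULL
  for (dx0 in c(0.2, 0.35, 0.5, 0.8, 1.2) * span / 2) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ (A1 - A2) / (1 + exp((pH - x0) / dx)) + A2,
        data = pts,
        start = list(A1 = pts$value[1L], A2 = pts$value[nrow(pts)],
                     x0 = stats::median(pts$pH), dx = dx0),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best))
    pf_stop("fit_error", "Boltzmann fit failed to converge from all starts")
  cf <- as.list(stats::coef(best))
  if (abs(cf$A1 - cf$A2) < 1e-8 * max(1, abs(cf$A1)))
    pf_stop("unidentifiability_error",
            "fitted sigmoid is flat (A1 ~ A2); parameters unidentifiable")
  out <- BoltzmannParams(cf$A1, cf$A2, cf$x0, cf$dx)
  attr(out, "residual") <- sqrt(stats::deviance(best))
  attr(out, "converged") <- isTRUE(best$convInfo$isConv)
  attr(out, "n_points") <- nrow(pts)
  out
}

# ---------------------------------------------------------------------------
# Electrode calibration
# ---------------------------------------------------------------------------

#' Calibrate a pH-sensitive microelectrode
#'
#' Ordinary least-squares line `pH = intercept + slope * V_e` through the
#' calibration readings (with exactly two points, the exact interpolant --
#' the paper's two-solution pH 7.0 / pH 6.4 calibration).
#'
#' @param points A data frame with columns `pH` and `value` (the recorded
#'   electrode potential in mV at each calibration pH); at least 2 points
#'   with distinct potentials.
#' @return An [ElectrodeCalibration] with attributes `r_squared` and
#'   `n_points`.
#' @export
calibrate_electrode <- function(points) {
  pts <- as_calibration_points(points, "calibrate_electrode")
  if (nrow(pts) < 2L)
    pf_stop("insufficient_data", "calibrate_electrode() needs >= 2 points")
  if (diff(range(pts$value)) == 0)
    pf_stop("singular_calibration",
            "all calibration potentials are identical; the line is singular")
  fit <- stats::lm(pH ~ value, data = pts)
  cf <- stats::coef(fit)
  out <- ElectrodeCalibration(slope = unname(cf[["value"]]),
                              intercept = unname(cf[["(Intercept)"]]))
  ss_tot <- sum((pts$pH - mean(pts$pH))^2)
  attr(out, "r_squared") <- if (ss_tot > 0)
    1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  attr(out, "n_points") <- nrow(pts)
  out
}

#' Convert an electrode potential trace to pH
#'
#' Element-wise affine map `pH = intercept + slope * V_e` over a
#' potential trace; the calibration used is recorded in the output metadata.
#'
#' @param trace A [Trace] of kind `"potential_mV"`.
#' @param cal An [ElectrodeCalibration].
#' @return A [Trace] of kind `"pH"`.
#' @export
voltage_to_ph <- function(trace, cal) {
  assert_kind(trace, "potential_mV", "voltage_to_ph")
  if (!inherits(cal, "ElectrodeCalibration"))
    pf_stop("type_error", "voltage_to_ph() expects an ElectrodeCalibration")
  Trace(trace$t, cal$intercept + cal$slope * trace$y, kind = "pH",
        meta = c(trace$meta, list(calibration = cal)))
}

#' Serialize a calibration result to JSON
#'
#' @param cal A [BoltzmannParams] or [ElectrodeCalibration].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  lst <- if (inherits(cal, "BoltzmannParams")) {
    list(type = "boltzmann", A1 = cal$A1, A2 = cal$A2, x0 = cal$x0,
         dx = cal$dx, residual = attr(cal, "residual"),
         n_points = attr(cal, "n_points"))
  } else if (inherits(cal, "ElectrodeCalibration")) {
    list(type = "electrode", slope = cal$slope, intercept = cal$intercept,
         r_squared = attr(cal, "r_squared"), n_points = attr(cal, "n_points"))
  } else {
    pf_stop("type_error", "write_calibration() expects a calibration object")
  }
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration result from JSON
#'
#' @param path Path written by [write_calibration()].
#' @return A [BoltzmannParams] or [ElectrodeCalibration].
#' @export
read_calibration <- function(path) {
  lst <- jsonlite::fromJSON(path)
  switch(lst$type %||% "",
         boltzmann = BoltzmannParams(lst$A1, lst$A2, lst$x0, lst$dx),
         electrode = ElectrodeCalibration(lst$slope, lst$intercept),
         pf_stop("parse_error",
                 sprintf("%s does not contain a recognised calibration", path)))
}
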