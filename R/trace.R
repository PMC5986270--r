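#' Time-series container for physiological recordings
#'
#' A `Trace` is the universal currency of the pipeline: a (possibly
#' irregularly sampled) scalar time series with a unit tag. The tag (`kind`)
#' records what the values are -- a fluorescence emission ratio, an electrode
#' potential in mV, a pH value, a proton concentration in nM, or the
#' log-enrichment statistic of the 18O-exchange assay -- and downstream
#' operations refuse inputs of the wrong kind rather than silently
#' misinterpreting them.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param y Numeric vector of measured values, same length as `t`, all finite.
#' @param kind One of `"ratio"`, `"potential_mV"`, `"pH"`, `"proton_nM"`,
#'   `"log_enrichment"`.
#' @param meta Named list of free-form provenance (ROI id, cell id, batch id,
#'   upstream processing notes). Carried along, never interpreted.
#'
#' @return An object of class `Trace`.
#' @examples
#' tr <- Trace(t = 0:9, y = 7.2 - 0.01 * (0:9), kind = "pH")
#' tr
#' @export
Trace <- function(t, y,
                  kind = c("ratio", "potential_mV", "pH", "proton_nM",
                           "log_enrichment"),
                  meta = list()) {
  kind <- match.arg(kind)
  if (!is.numeric(t) || !is.numeric(y))
    pf_stop("validation_error", "`t` and `y` must be numeric vectors")
  t <- as.double(t); y <- as.double(y)
  if (length(t) != length(y))
    pf_stop("validation_error",
            sprintf("`t` (%d) and `y` (%d) must have the same length",
                    length(t), length(y)))
  if (length(t) == 0L)
    pf_stop("validation_error", "a Trace must contain at least one sample")
  if (anyNA(t) || any(!is.finite(t)))
    pf_stop("validation_error", "`t` contains non-finite values")
  if (anyNA(y) || any(!is.finite(y)))
    pf_stop("validation_error", "`y` contains non-finite values")
  if (length(t) > 1L && any(diff(t) <= 0))
    pf_stop("validation_error",
            sprintf("`t` must be strictly increasing (first violation after t = %g s)",
                    t[which(diff(t) <= 0)[1L]]))
  if (!is.list(meta)) pf_stop("validation_error", "`meta` must be a list")
  structure(list(t = t, y = y, kind = kind, meta = meta), class = "Trace")
}

#' @export
print.Trace <- function(x, ...) {
  cat(sprintf("<Trace[%s]> %d samples, t = %g..%g s, y in [%g, %g]\n",
              x$kind, length(x$t), x$t[1L], x$t[length(x$t)],
              min(x$y), max(x$y)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.Trace <- function(x) length(x$t)

#' @export
as.data.frame.Trace <- function(x, ...) data.frame(t = x$t, y = x$y)

is_trace <- function(x) inherits(x, "Trace")

assert_kind <- function(trace, kind, op) {
  if (!is_trace(trace))
    pf_stop("type_error", sprintf("%s() expects a Trace", op))
  if (trace$kind != kind)
    pf_stop("type_error",
            sprintf("%s() expects a Trace of kind '%s', got '%s'",
                    op, kind, trace$kind))
  invisible(trace)
}

# ---------------------------------------------------------------------------
# Delimited-text I/O
# ---------------------------------------------------------------------------

# Split a line on the detected delimiter. Comma and tab are auto-detected;
# otherwise any run of whitespace separates fields. Decimal point only.
detect_delim <- function(lines) {
  if (any(grepl(",", lines, fixed = TRUE))) return(",")
  if (any(grepl("\t", lines, fixed = TRUE))) return("\t")
  "[[:space:]]+"
}

parse_numeric_table <- function(path, n_cols, what) {
  if (!file.exists(path))
    pf_stop("io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    pf_stop("parse_error", sprintf("%s: no data rows in %s", what, path))
  delim <- detect_delim(lines[idx])
  split1 <- function(s) {
    f <- strsplit(trimws(s), delim)[[1L]]
    f[nzchar(f)]
  }
  first <- split1(lines[idx[1L]])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) idx <- idx[-1L]
  if (!length(idx))
    pf_stop("parse_error", sprintf("%s: header but no data rows in %s", what, path))
  out <- matrix(NA_real_, nrow = length(idx), ncol = n_cols)
  for (i in seq_along(idx)) {
    f <- split1(lines[idx[i]])
    if (length(f) < n_cols)
      pf_stop("parse_error",
              sprintf("%s: line %d of %s has %d field(s), expected %d",
                      what, idx[i], path, length(f), n_cols))
    v <- suppressWarnings(as.numeric(f[seq_len(n_cols)]))
    if (anyNA(v))
      pf_stop("parse_error",
              sprintf("%s: malformed numeric value on line %d of %s",
                      what, idx[i], path))
    out[i, ] <- v
  }
  out
}

#' Read a trace from delimited text
#'
#' Reads a two-column delimited text file (time in seconds, value). Comma or
#' tab delimiters are auto-detected; a single header line is permitted and
#' skipped; lines beginning with `#` are comments. Malformed rows raise a
#' parse error naming the offending line; non-monotone time raises a
#' validation error.
#'
#' @param path Path to the file.
#' @inheritParams Trace
#' @return A [Trace].
#' @export
read_trace <- function(path,
                       kind = c("ratio", "potential_mV", "pH", "proton_nM",
                                "log_enrichment")) {
  kind <- match.arg(kind)
  m <- parse_numeric_table(path, 2L, "read_trace")
  Trace(m[, 1L], m[, 2L], kind = kind, meta = list(source = path))
}

#' Write a trace to delimited text
#'
#' Writes `t,value` CSV at full double precision, so that
#' `read_trace(write_trace(x))` reproduces `x` exactly.
#'
#' @param trace A [Trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!is_trace(trace)) pf_stop("type_error", "write_trace() expects a Trace")
  lines <- c("t,value",
             sprintf("%.17g,%.17g", trace$t, trace$y))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Application protocols
# ---------------------------------------------------------------------------

#' Solution-change protocol for an experiment
#'
#' An `ApplicationProtocol` is the ordered list of solution-change events
#' (which solute, at what concentration, applied when) that defines the
#' analysis windows of a recording: lactate pulses for transport-rate
#' extraction and the terminal CO2/HCO3- pulse for buffer-capacity
#' determination.
#'
#' @param events A data frame with columns `solute` (character),
#'   `concentration` (mM, or percent CO2 for gas events), `start` and `end`
#'   (seconds). Events of the same solute must not overlap.
#' @param baseline Label of the baseline (non-event) superfusate.
#' @return An object of class `ApplicationProtocol`.
#' @examples
#' ApplicationProtocol(data.frame(
#'   solute = c("lactate", "lactate", "CO2"),
#'   concentration = c(3, 10, 5),
#'   start = c(300, 900, 1500),
#'   end = c(600, 1200, 1800)))
#' @export
ApplicationProtocol <- function(events, baseline = "control") {
  if (!is.data.frame(events))
    pf_stop("validation_error", "`events` must be a data frame")
  need <- c("solute", "concentration", "start", "end")
  if (!all(need %in% names(events)))
    pf_stop("validation_error",
            paste("`events` must have columns", paste(need, collapse = ", ")))
  if (!nrow(events))
    pf_stop("validation_error", "`events` must contain at least one event")
  events$solute <- as.character(events$solute)
  for (col in c("concentration", "start", "end"))
    events[[col]] <- as.double(events[[col]])
  if (any(!is.finite(unlist(events[c("concentration", "start", "end")]))))
    pf_stop("validation_error", "event fields must be finite")
  if (any(events$concentration < 0))
    pf_stop("validation_error", "concentrations must be >= 0")
  if (any(events$start >= events$end))
    pf_stop("validation_error", "every event needs start < end")
  for (s in unique(events$solute)) {
    ev <- events[events$solute == s, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$start[-1L] < ev$end[-nrow(ev)]))
      pf_stop("validation_error",
              sprintf("overlapping events for solute '%s'", s))
  }
  events <- events[order(events$start), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, baseline = as.character(baseline)),
            class = "ApplicationProtocol")
}

#' @export
print.ApplicationProtocol <- function(x, ...) {
  cat(sprintf("<ApplicationProtocol> %d event(s), baseline '%s'\n",
              nrow(x$events), x$baseline))
  print(x$events)
  invisible(x)
}

is_co2_event <- function(solute) grepl("co2", solute, ignore.case = TRUE)

#' Read an application protocol from YAML or JSON
#'
#' The file holds either a bare list of events or a mapping with keys
#' `events` and (optionally) `baseline`; each event has keys `solute`,
#' `concentration`, `start`, `end`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [ApplicationProtocol].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    pf_stop("io_error", sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  baseline <- "control"
  events <- raw
  if (!is.null(names(raw)) && "events" %in% names(raw)) {
    events <- raw$events
    baseline <- raw$baseline %||% baseline
  }
  if (!length(events))
    pf_stop("parse_error", sprintf("no events found in %s", path))
  df <- do.call(rbind, lapply(events, function(e) {
    for (k in c("solute", "concentration", "start", "end"))
      if (is.null(e[[k]]))
        pf_stop("parse_error",
                sprintf("event in %s is missing key '%s'", path, k))
    data.frame(solute = as.character(e$solute),
               concentration = as.numeric(e$concentration),
               start = as.numeric(e$start), end = as.numeric(e$end))
  }))
  ApplicationProtocol(df, baseline = baseline)
}

#' Write an application protocol to YAML or JSON
#'
#' @param protocol An [ApplicationProtocol].
#' @param path Output path; format chosen by extension (`.json` vs YAML).
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  if (!inherits(protocol, "ApplicationProtocol"))
    pf_stop("type_error", "write_protocol() expects an ApplicationProtocol")
  ev <- protocol$events
  lst <- list(baseline = protocol$baseline,
              events = lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ])))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Extract the sub-trace around a protocol event
#'
#' Returns the samples of `trace` falling in `[start - pad_s, end + pad_s]`
#' for the chosen event, clipped to the trace support. Samples are never
#' reordered or altered; the event is recorded in the sub-trace's metadata.
#'
#' @param trace A [Trace].
#' @param protocol An [ApplicationProtocol].
#' @param event_index Row index into `protocol$events`.
#' @param pad_s Padding in seconds added on both sides of the event window.
#' @return A [Trace] of the same kind.
#' @export
segment_trace <- function(trace, protocol, event_index, pad_s = 0) {
  if (!is_trace(trace)) pf_stop("type_error", "segment_trace() expects a Trace")
  if (!inherits(protocol, "ApplicationProtocol"))
    pf_stop("type_error", "segment_trace() expects an ApplicationProtocol")
  stopifnot_number(event_index, "event_index")
  stopifnot_number(pad_s, "pad_s")
  if (event_index < 1 || event_index > nrow(protocol$events))
    pf_stop("window_error",
            sprintf("event_index %d out of range (protocol has %d events)",
                    event_index, nrow(protocol$events)))
  ev <- protocol$events[event_index, ]
  lo <- ev$start - pad_s
  hi <- ev$end + pad_s
  idx <- trace$t >= lo & trace$t <= hi
  if (!any(idx))
    pf_stop("window_error",
            sprintf("event window [%g, %g] s does not intersect trace support [%g, %g] s",
                    lo, hi, trace$t[1L], trace$t[length(trace$t)]))
  Trace(trace$t[idx], trace$y[idx], kind = trace$kind,
        meta = c(trace$meta,
                 list(event = list(solute = ev$solute,
                                   concentration = ev$concentration,
                                   start = ev$start, end = ev$end,
                                   pad_s = pad_s))))
}

# Internal: sub-trace over an arbitrary time window (inclusive bounds).
window_trace <- function(trace, lo, hi, what = "window_trace") {
  idx <- trace$t >= lo & trace$t <= hi
  if (!any(idx))
    pf_stop("window_error",
            sprintf("%s: window [%g, %g] s does not intersect trace", what, lo, hi))
  Trace(trace$t[idx], trace$y[idx], kind = trace$kind, meta = trace$meta)
}

# ---------------------------------------------------------------------------
# Solution composition
# ---------------------------------------------------------------------------

#' CO2/bicarbonate composition of a superfusate
#'
#' Describes the CO2/HCO3- system of an applied solution: the gas fraction,
#' the bicarbonate concentration, the solution pH, and the apparent pK of the
#' CO2 hydration equilibrium used by Henderson-Hasselbalch conversions.
#' The default is the 5% CO2 / 10 mM HCO3- pulse solution at pH 7.0 with
#' pK' = 6.1 (the physiological-chemistry convention at room temperature).
#'
#' @param pco2_fraction CO2 gas fraction, dimensionless in `[0, 1]`.
#' @param hco3_mM Bicarbonate concentration of the solution, mM.
#' @param pH_o Extracellular (solution) pH.
#' @param pK_prime Apparent pK of CO2/HCO3-, pH units.
#' @param temperature_C Temperature, degrees Celsius (bookkeeping only).
#' @return An object of class `SolutionSpec`.
#' @export
SolutionSpec <- function(pco2_fraction = 0.05, hco3_mM = 10, pH_o = 7.0,
                         pK_prime = 6.1, temperature_C = 24) {
  stopifnot_number(pco2_fraction, "pco2_fraction")
  stopifnot_number(hco3_mM, "hco3_mM")
  stopifnot_number(pH_o, "pH_o")
  stopifnot_number(temperature_C, "temperature_C")
  if (pco2_fraction < 0 || pco2_fraction > 1)
    pf_stop("validation_error", "`pco2_fraction` must be in [0, 1]")
  if (hco3_mM < 0)
    pf_stop("validation_error", "`hco3_mM` must be >= 0")
  if (is.null(pK_prime) || is.na(pK_prime))
    pf_stop("configuration_error", "`pK_prime` must be supplied")
  stopifnot_number(pK_prime, "pK_prime")
  structure(list(pco2_fraction = pco2_fraction, hco3_mM = hco3_mM,
                 pH_o = pH_o, pK_prime = pK_prime,
                 temperature_C = temperature_C),
            class = "SolutionSpec")
}

#' @export
print.SolutionSpec <- function(x, ...) {
  cat(sprintf("<SolutionSpec> %.1f%% CO2, %g mM HCO3-, pH_o %.2f, pK' %.2f, %g degC\n",
              100 * x$pco2_fraction, x$hco3_mM, x$pH_o, x$pK_prime,
              x$temperature_C))
  invisible(x)
}
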