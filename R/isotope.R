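#' Ion-current abundances of the 18O-exchange assay
#'
#' Time series of the three 13C-CO2 isotopologue abundances monitored by the
#' mass spectrometer: doubly labelled 13C18O18O (m/z 49), the intermediate
#' 13C18O16O (m/z 47) and the end product 13C16O16O (m/z 45). Abundances are
#' arbitrary ion-current units; the log-enrichment statistic is
#' scale-invariant.
#'
#' @param t Sample times, seconds, strictly increasing.
#' @param a45,a47,a49 Abundances at m/z 45, 47, 49; non-negative, with a
#'   positive total at every sample.
#' @return An object of class `IsotopeSeries`.
#' @export
IsotopeSeries <- function(t, a45, a47, a49) {
  if (!is.numeric(t) || !is.numeric(a45) || !is.numeric(a47) || !is.numeric(a49))
    pf_stop("validation_error", "all IsotopeSeries fields must be numeric")
  n <- length(t)
  if (length(a45) != n || length(a47) != n || length(a49) != n)
    pf_stop("validation_error", "t, a45, a47, a49 must have equal lengths")
  if (n == 0L)
    pf_stop("validation_error", "an IsotopeSeries needs at least one sample")
  if (any(!is.finite(t)) || (n > 1L && any(diff(t) <= 0)))
    pf_stop("validation_error", "`t` must be finite and strictly increasing")
  for (nm in c("a45", "a47", "a49")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0))
      pf_stop("validation_error",
              sprintf("`%s` must be finite and non-negative", nm))
  }
  total <- a45 + a47 + a49
  if (any(total <= 0))
    pf_stop("validation_error",
            sprintf("total abundance must be positive at every sample (first violation at t = %g s)",
                    t[which(total <= 0)[1L]]))
  structure(list(t = as.double(t), a45 = as.double(a45),
                 a47 = as.double(a47), a49 = as.double(a49)),
            class = "IsotopeSeries")
}

#' @export
print.IsotopeSeries <- function(x, ...) {
  cat(sprintf("<IsotopeSeries> %d samples, t = %g..%g s\n",
              length(x$t), x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' Read an isotope series from delimited text
#'
#' Four columns: time (s), abundance at m/z 45, 47 and 49. Delimiter and
#' header handling as in [read_trace()].
#'
#' @param path Path to the file.
#' @return An [IsotopeSeries].
#' @export
read_isotope_series <- function(path) {
  m <- parse_numeric_table(path, 4L, "read_isotope_series")
  IsotopeSeries(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
}

#' Write an isotope series to delimited text
#'
#' @param series An [IsotopeSeries].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_series <- function(series, path) {
  if (!inherits(series, "IsotopeSeries"))
    pf_stop("type_error", "write_isotope_series() expects an IsotopeSeries")
  lines <- c("t,a45,a47,a49",
             sprintf("%.17g,%.17g,%.17g,%.17g",
                     series$t, series$a45, series$a47, series$a49))
  writeLines(lines, path)
  invisible(path)
}

#' Log-enrichment statistic of an isotope series
#'
#' `LE = log10(a49 * 100 / (a49 + a47 + a45))`: the (log of the) percentage
#' of doubly 18O-labelled CO2 among all 13C-CO2 species. LE is invariant to
#' overall abundance scaling, equals 2 for pure m/z 49, and in a first-order
#' exchange cascade decays linearly in time with slope `-2 theta / ln(10)`
#' (per second), where `theta` is the per-18O-atom exchange rate. Samples
#' with zero m/z-49 abundance (LE undefined) are dropped; their count is
#' recorded in the output metadata.
#'
#' @param series An [IsotopeSeries].
#' @return A [Trace] of kind `"log_enrichment"`; `meta$n_dropped` counts
#'   discarded zero-a49 samples.
#' @export
log_enrichment <- function(series) {
  if (!inherits(series, "IsotopeSeries"))
    pf_stop("type_error", "log_enrichment() expects an IsotopeSeries")
  keep <- series$a49 > 0
  if (!any(keep))
    pf_stop("validation_error",
            "all samples have zero m/z-49 abundance; log enrichment is undefined")
  total <- series$a45 + series$a47 + series$a49
  le <- log10(series$a49[keep] * 100 / total[keep])
  Trace(series$t[keep], le, kind = "log_enrichment",
        meta = list(n_dropped = sum(!keep)))
}

#' Depletion rate of the log enrichment over a time window
#'
#' Ordinary least-squares slope of the log-enrichment trace over
#' `[t_a, t_b]`, reported per minute. Negative slopes indicate 18O
#' depletion; the uncatalyzed and the lysate-catalyzed phases of a recording
#' are fitted separately and compared by [ca_units()].
#'
#' @param le A [Trace] of kind `"log_enrichment"`.
#' @param window `c(t_a, t_b)` in seconds; must contain at least 3 samples.
#' @return Slope in LE units per minute, with attributes `r2` and `n`.
#' @export
enrichment_rate <- function(le, window) {
  assert_kind(le, "log_enrichment", "enrichment_rate")
  if (!is.numeric(window) || length(window) != 2L || window[1L] >= window[2L])
    pf_stop("validation_error", "`window` must be c(t_a, t_b) with t_a < t_b")
  idx <- le$t >= window[1L] & le$t <= window[2L]
  if (sum(idx) < 3L)
    pf_stop("insufficient_data",
            sprintf("window [%g, %g] s contains %d sample(s), need >= 3",
                    window[1L], window[2L], sum(idx)))
  f <- ols_slope(le$t[idx], le$y[idx])
  structure(f$slope * 60, r2 = f$r2, n = sum(idx))
}

#' Carbonic anhydrase activity in enzyme units
#'
#' Converts the catalyzed and uncatalyzed log-enrichment depletion rates
#' into enzyme units: one unit corresponds to 100% stimulation of the
#' non-catalyzed 18O depletion, i.e.
#' `units = |cat_rate| / |uncat_rate| - 1`. A catalyzed rate exactly twice
#' the uncatalyzed rate is therefore exactly 1 U. Units are additionally
#' normalised per ml of lysate (default 0.08 ml, a batch of 20 oocytes lysed
#' in 80 ul of saline).
#'
#' @param cat_rate Catalyzed LE depletion rate, LE units/min (negative).
#' @param uncat_rate Uncatalyzed LE depletion rate, LE units/min (negative,
#'   nonzero).
#' @param sample_volume_ml Lysate volume used for the per-ml normalisation.
#' @return An object of class `CAActivityResult`: list with `uncat_rate`,
#'   `cat_rate`, `units` (floored at 0), `units_raw` (unfloored),
#'   `negative_flagged`, `units_per_ml`, `sample_volume_ml`.
#' @export
ca_units <- function(cat_rate, uncat_rate, sample_volume_ml = 0.08) {
  cat_rate <- as.numeric(cat_rate); uncat_rate <- as.numeric(uncat_rate)
  stopifnot_number(cat_rate, "cat_rate")
  stopifnot_number(uncat_rate, "uncat_rate")
  stopifnot_number(sample_volume_ml, "sample_volume_ml")
  if (uncat_rate == 0)
    pf_stop("division_error", "uncatalyzed rate is zero; units are undefined")
  if (sample_volume_ml <= 0)
    pf_stop("validation_error", "`sample_volume_ml` must be positive")
  if (cat_rate * uncat_rate < 0)
    pf_stop("inconsistent_assay",
            sprintf("catalyzed (%.4g) and uncatalyzed (%.4g) rates have opposite signs",
                    cat_rate, uncat_rate))
  units_raw <- abs(cat_rate) / abs(uncat_rate) - 1
  negative <- units_raw < 0
  units <- max(units_raw, 0)
  structure(list(uncat_rate = uncat_rate, cat_rate = cat_rate,
                 units = units, units_raw = units_raw,
                 negative_flagged = negative,
                 units_per_ml = units / sample_volume_ml,
                 sample_volume_ml = sample_volume_ml),
            class = "CAActivityResult")
}

#' @export
print.CAActivityResult <- function(x, ...) {
  cat(sprintf("<CAActivityResult> %.4g U (%.4g U/ml at %g ml); rates: uncat %.4g, cat %.4g LE/min%s\n",
              x$units, x$units_per_ml, x$sample_volume_ml,
              x$uncat_rate, x$cat_rate,
              if (x$negative_flagged) " [flagged: catalyzed slower than uncatalyzed]" else ""))
  invisible(x)
}

#' Full 18O-exchange assay on one recording
#'
#' Computes the log enrichment, fits the uncatalyzed depletion rate over the
#' pre-addition window and the catalyzed rate over the post-addition window
#' (the paper follows the catalyzed reaction for 10 minutes after lysate
#' addition), and converts the two rates to enzyme units.
#'
#' @param series An [IsotopeSeries].
#' @param addition_time_s Time (s) at which the lysate was added.
#' @param sample_volume_ml Lysate volume in ml for per-ml units.
#' @param pre_window,post_window Optional `c(t_a, t_b)` regression windows;
#'   defaults are the whole record before the addition and the 600 s
#'   (clipped to the record) after it.
#' @return A [CAActivityResult]; the two fitted windows are attached as the
#'   `"windows"` attribute.
#' @export
ca_assay <- function(series, addition_time_s, sample_volume_ml = 0.08,
                     pre_window = NULL, post_window = NULL) {
  if (!inherits(series, "IsotopeSeries"))
    pf_stop("type_error", "ca_assay() expects an IsotopeSeries")
  stopifnot_number(addition_time_s, "addition_time_s")
  t0 <- series$t[1L]; t1 <- series$t[length(series$t)]
  if (addition_time_s <= t0 || addition_time_s >= t1)
    pf_stop("window_error",
            "`addition_time_s` must fall strictly inside the recording")
  le <- log_enrichment(series)
  pre_window <- pre_window %||% c(t0, addition_time_s)
  post_window <- post_window %||% c(addition_time_s, min(t1, addition_time_s + 600))
  uncat <- enrichment_rate(le, pre_window)
  cat_r <- enrichment_rate(le, post_window)
  out <- ca_units(cat_r, uncat, sample_volume_ml = sample_volume_ml)
  attr(out, "windows") <- list(uncatalyzed = pre_window, catalyzed = post_window)
  out
}
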