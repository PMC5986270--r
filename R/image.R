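#' 8-bit grayscale nuclei image
#'
#' A single-channel fluorescence image of stained nuclei (e.g. Hoechst),
#' stored as a matrix of intensities in `[0, 255]` plus the physical pixel
#' size needed to convert counts to nuclei per square millimetre.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param pixel_size_um Pixel edge length, micrometres per pixel (> 0).
#' @return An object of class `NucleiImage`.
#' @export
NucleiImage <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    pf_stop("validation_error", "`pixels` must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    pf_stop("validation_error", "intensities must lie in [0, 255]")
  stopifnot_number(pixel_size_um, "pixel_size_um")
  if (pixel_size_um <= 0)
    pf_stop("validation_error", "`pixel_size_um` must be positive")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "NucleiImage")
}

#' @export
print.NucleiImage <- function(x, ...) {
  cat(sprintf("<NucleiImage> %d x %d px at %g um/px (%.3g mm^2), intensities %g..%g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              length(x$pixels) * x$pixel_size_um^2 * 1e-6,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an 8-bit grayscale image as a NucleiImage
#'
#' Reads PNG or TIFF via EBImage; multi-channel images are rejected (the
#' counting pipeline takes the single stained channel as input).
#'
#' @param path Path to a PNG or TIFF file.
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @return A [NucleiImage].
#' @export
read_nuclei_image <- function(path, pixel_size_um) {
  if (!file.exists(path))
    pf_stop("io_error", sprintf("file not found: %s", path))
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2L && d[3L] > 1L)
    pf_stop("validation_error",
            sprintf("%s has %d channels; supply a single-channel image", path, d[3L]))
  m <- EBImage::imageData(img)
  m <- round(matrix(as.double(m), nrow = dim(img)[1L]) * 255)
  NucleiImage(m, pixel_size_um)
}

#' Write a NucleiImage to PNG or TIFF
#'
#' @param image A [NucleiImage].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_nuclei_image <- function(image, path) {
  if (!inherits(image, "NucleiImage"))
    pf_stop("type_error", "write_nuclei_image() expects a NucleiImage")
  EBImage::writeImage(EBImage::Image(image$pixels / 255), path)
  invisible(path)
}

#' Size and circularity filter for particle counting
#'
#' The acceptance window of the particle counter: objects whose pixel area
#' lies in `[size_min, size_max]` and whose circularity
#' `4 * pi * area / perimeter^2` (clamped to 1) lies in
#' `[circ_min, circ_max]` are counted. The pass-all filter
#' (`0..Inf`, `0..1`) reproduces the "count everything" setting.
#'
#' @param size_min,size_max Area bounds in pixels (max may be `Inf`).
#' @param circ_min,circ_max Circularity bounds in `[0, 1]`.
#' @return An object of class `ParticleFilter`.
#' @export
ParticleFilter <- function(size_min = 0, size_max = Inf,
                           circ_min = 0, circ_max = 1) {
  stopifnot_number(size_min, "size_min")
  stopifnot_number(size_max, "size_max", finite = FALSE)
  stopifnot_number(circ_min, "circ_min")
  stopifnot_number(circ_max, "circ_max")
  if (size_min > size_max)
    pf_stop("validation_error", "`size_min` must be <= `size_max`")
  if (circ_min < 0 || circ_max > 1 || circ_min > circ_max)
    pf_stop("validation_error",
            "circularity bounds must satisfy 0 <= circ_min <= circ_max <= 1")
  structure(list(size_min = size_min, size_max = size_max,
                 circ_min = circ_min, circ_max = circ_max),
            class = "ParticleFilter")
}

# ---------------------------------------------------------------------------
# Labelling helpers
# ---------------------------------------------------------------------------

# 8-connected labelling: EBImage::bwlabel() is 4-connected, so labels that
# touch only diagonally are merged afterwards with a small union-find over
# the label ids.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal neighbours
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]   # down-left diagonal neighbours
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d]))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0] <- relab[out[out > 0]]
  out
}

relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  out <- lab
  out[out > 0] <- match(out[out > 0], ids)
  out
}

# Crofton perimeter of a binary mask (4-direction approximation).
# Each 2x2 pixel neighbourhood is encoded as a 4-bit configuration and the
# perimeter is the configuration histogram dotted with integral-geometry
# weights; for smooth convex objects this tracks the true perimeter to ~1%.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  a <- m[2:nr, 2:nc]        # current pixel
  b <- m[2:nr, 1:(nc - 1)]  # left
  cc <- m[1:(nr - 1), 2:nc] # up
  d <- m[1:(nr - 1), 1:(nc - 1)]  # up-left
  code <- a + 4L * b + 2L * cc + 8L * d
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(h * coefs)
}

# ---------------------------------------------------------------------------
# Segmentation and counting
# ---------------------------------------------------------------------------

#' Segment nuclei by thresholding and watershed splitting
#'
#' Reproduces the standard counting pipeline: pixels with intensity in
#' `[threshold_lo, threshold_hi]` form the binary mask (the 30-255 threshold
#' of an 8-bit Hoechst channel); touching nuclei are optionally split by a
#' watershed on the Euclidean distance transform; connected components are
#' labelled with 8-connectivity.
#'
#' @param image A [NucleiImage].
#' @param threshold_lo,threshold_hi Intensity window, `lo < hi <= 255`.
#' @param split_touching Apply the distance-transform watershed to separate
#'   fused nuclei.
#' @param peak_tolerance Watershed tolerance: minimum depth (in distance
#'   units, i.e. pixels) of the saddle separating two peaks for them to
#'   found separate objects.
#' @param peak_ext Neighbourhood radius (pixels) used when detecting
#'   distance-map maxima; roughly half the expected nucleus radius is a
#'   sensible value for strongly overlapping nuclei.
#' @return An integer label matrix (0 = background), sequentially labelled.
#' @export
segment_nuclei <- function(image, threshold_lo = 30, threshold_hi = 255,
                           split_touching = TRUE,
                           peak_tolerance = 1, peak_ext = 1) {
  if (!inherits(image, "NucleiImage"))
    pf_stop("type_error", "segment_nuclei() expects a NucleiImage")
  stopifnot_number(threshold_lo, "threshold_lo")
  stopifnot_number(threshold_hi, "threshold_hi")
  if (!(threshold_lo < threshold_hi && threshold_hi <= 255))
    pf_stop("validation_error",
            "thresholds must satisfy threshold_lo < threshold_hi <= 255")
  mask <- image$pixels >= threshold_lo & image$pixels <= threshold_hi
  storage.mode(mask) <- "integer"
  if (!any(mask > 0))
    return(matrix(0L, nrow(mask), ncol(mask)))
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = peak_tolerance, ext = peak_ext)
    lab <- matrix(as.integer(lab), nrow = nrow(mask))
  } else {
    lab <- label8(mask)
  }
  relabel_sequential(lab)
}

#' Per-object geometry of a label image
#'
#' Area (pixel count), Crofton perimeter and clamped circularity
#' `min(1, 4 * pi * area / perimeter^2)` for every labelled object.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @return A data frame with columns `label`, `area`, `perimeter`,
#'   `circularity`.
#' @export
particle_stats <- function(labels) {
  if (!is.matrix(labels))
    pf_stop("type_error", "particle_stats() expects a label matrix")
  pos <- which(labels > 0)
  if (!length(pos))
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), circularity = numeric()))
  nr <- nrow(labels)
  by_label <- split(pos, labels[pos])
  rows <- lapply(names(by_label), function(id) {
    px <- by_label[[id]]
    r <- ((px - 1L) %% nr) + 1L
    cl <- ((px - 1L) %/% nr) + 1L
    sub <- matrix(0L, max(r) - min(r) + 1L, max(cl) - min(cl) + 1L)
    sub[cbind(r - min(r) + 1L, cl - min(cl) + 1L)] <- 1L
    per <- crofton_perimeter(sub)
    area <- length(px)
    data.frame(label = as.integer(id), area = area, perimeter = per,
               circularity = min(1, 4 * pi * area / per^2))
  })
  out <- do.call(rbind, rows)
  out[order(out$label), , drop = FALSE]
}

#' Count particles passing a size/circularity filter
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param filter A [ParticleFilter]; the default passes everything.
#' @return Integer count; the per-object geometry table is attached as the
#'   `"particles"` attribute.
#' @export
count_particles <- function(labels, filter = ParticleFilter()) {
  if (!inherits(filter, "ParticleFilter"))
    pf_stop("type_error", "count_particles() expects a ParticleFilter")
  st <- particle_stats(labels)
  pass <- st$area >= filter$size_min & st$area <= filter$size_max &
    st$circularity >= filter$circ_min & st$circularity <= filter$circ_max
  structure(sum(pass), particles = cbind(st, pass = pass))
}

#' Convert a nuclei count to nuclei per square millimetre
#'
#' `count / (height * width * pixel_size_um^2 * 1e-6)`.
#'
#' @param count Number of nuclei in the image.
#' @param image The [NucleiImage] the count came from (supplies the pixel
#'   size and dimensions).
#' @return Nuclei per mm^2.
#' @export
nuclei_density <- function(count, image) {
  if (!inherits(image, "NucleiImage"))
    pf_stop("type_error", "nuclei_density() expects a NucleiImage")
  count <- as.numeric(count)
  stopifnot_number(count, "count")
  px <- image$pixel_size_um
  if (is.null(px) || is.na(px) || px <= 0)
    pf_stop("configuration_error", "pixel size is missing or invalid")
  area_mm2 <- length(image$pixels) * px^2 * 1e-6
  count / area_mm2
}

# ---------------------------------------------------------------------------
# Small assay-quantification formulas
# ---------------------------------------------------------------------------

#' Relative gene expression by the comparative threshold (2^-ddCt) method
#'
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,cal - Ct_ref,cal))`.
#' One extra cycle of the target in the sample (ddCt = 1) halves the fold
#' change.
#'
#' @param ct_target_sample,ct_ref_sample Ct cycles of target and reference
#'   gene in the sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct cycles in the
#'   calibrator.
#' @return Fold change relative to the calibrator.
#' @export
fold_change_ddct <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  for (v in list(ct_target_sample, ct_ref_sample, ct_target_calibrator,
                 ct_ref_calibrator))
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      pf_stop("validation_error", "all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Loading-normalised band intensity relative to a reference lane
#'
#' `(target/loading) / (reference_target/reference_loading)`: the band
#' signal normalised to its loading control, expressed as a fraction of the
#' same quantity in the reference lane (multiply by 100 for percent).
#'
#' @param target_signal,loading_signal Band and loading-control intensities
#'   in the lane of interest.
#' @param reference_target,reference_loading The same pair in the reference
#'   lane.
#' @return Relative intensity (1 = identical to reference).
#' @export
normalized_band_intensity <- function(target_signal, loading_signal,
                                      reference_target, reference_loading) {
  for (nm in c("loading_signal", "reference_target", "reference_loading")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(v <= 0))
      pf_stop("validation_error", sprintf("`%s` must be positive", nm))
  }
  if (!is.numeric(target_signal) || anyNA(target_signal) || any(target_signal < 0))
    pf_stop("validation_error", "`target_signal` must be non-negative")
  (target_signal / loading_signal) / (reference_target / reference_loading)
}

#' Proximity-ligation signals per nucleus
#'
#' @param n_signals Number of detected dots (>= 0).
#' @param n_nuclei Number of nuclei (> 0).
#' @return Signals per nucleus.
#' @export
signals_per_nucleus <- function(n_signals, n_nuclei) {
  stopifnot_number(n_signals, "n_signals")
  stopifnot_number(n_nuclei, "n_nuclei")
  if (n_signals < 0)
    pf_stop("validation_error", "`n_signals` must be >= 0")
  if (n_nuclei <= 0)
    pf_stop("division_error", "`n_nuclei` must be positive")
  n_signals / n_nuclei
}
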