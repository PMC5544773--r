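#' Preprocessing configuration
#'
#' Parameters of the measurement conditioning chain: replicate averaging,
#' linear baseline correction through low-absorption anchor windows, peak
#' normalization to the O-H stretch near 3 um, excision of the atmospheric
#' CO2 doublet, and Savitzky-Golay smoothing for differential outputs.
#'
#' Wavelength windows are in um.  Defaults: anchors at 1.8--2.2 um and
#' 7.3--7.5 um (low-absorption windows of liquid water), CO2 band
#' 4.20--4.35 um (asymmetric-stretch doublet), O-H window 2.85--3.15 um,
#' Savitzky-Golay window 5 points with a cubic polynomial.
#'
#' @param baseline_anchor_bands list of `c(lo, hi)` wavelength intervals
#'   assumed absorption-free, used to fit the linear (in wavenumber)
#'   baseline.
#' @param co2_band `c(lo, hi)` wavelength interval to excise.
#' @param oh_peak_window `c(lo, hi)` window containing the 3 um maximum.
#' @param sg_window odd integer, Savitzky-Golay window length in points.
#' @param sg_order polynomial order, `< sg_window`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_anchor_bands = list(c(1.8, 2.2),
                                                           c(7.3, 7.5)),
                              co2_band = c(4.20, 4.35),
                              oh_peak_window = c(2.85, 3.15),
                              sg_window = 5L, sg_order = 3L) {
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  if (sg_window %% 2L != 1L || sg_window <= sg_order)
    stop_argument("sg_window must be odd and greater than sg_order")
  if (!is.list(baseline_anchor_bands))
    baseline_anchor_bands <- list(baseline_anchor_bands)
  for (b in baseline_anchor_bands)
    if (length(b) != 2 || b[1] >= b[2])
      stop_argument("each anchor band must be c(lo, hi) with lo < hi")
  if (length(co2_band) != 2 || co2_band[1] >= co2_band[2])
    stop_argument("co2_band must be c(lo, hi) with lo < hi")
  structure(list(baseline_anchor_bands = baseline_anchor_bands,
                 co2_band = co2_band, oh_peak_window = oh_peak_window,
                 sg_window = sg_window, sg_order = sg_order),
            class = "preprocess_config")
}

band_points <- function(axis, band) {
  wl <- axis_wavelength(axis)
  which(wl >= band[1] & wl <= band[2])
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate measurements taken on identical
#' axes with the same reference and reflection count.
#'
#' @param spectra a list of [absorbance_spectrum()] objects (or a single
#'   spectrum, returned unchanged).
#' @return An [absorbance_spectrum()].
#' @export
average_replicates <- function(spectra) {
  if (inherits(spectra, "absorbance_spectrum")) return(spectra)
  if (!length(spectra)) stop_argument("need at least one spectrum")
  first <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!axes_equal(s$axis, first$axis))
      stop_argument("replicates must share the same axis")
    if (s$reference != first$reference ||
        s$n_reflections != first$n_reflections)
      stop_argument("replicates must share reference and n_reflections")
  }
  a <- Reduce(`+`, lapply(spectra, `[[`, "a")) / length(spectra)
  absorbance_spectrum(first$axis, a, reference = first$reference,
                      n_reflections = first$n_reflections)
}

#' Subtract a linear baseline fitted to anchor windows
#'
#' A straight line in wavenumber is least-squares fitted through the
#' (mean wavenumber, mean absorbance) point of each anchor band and
#' subtracted; with a single band a constant is subtracted.  The corrected
#' spectrum has zero mean over each anchor band (exactly so with one or two
#' bands) and the operation is idempotent for fixed anchors.
#'
#' @param spectrum an [absorbance_spectrum()].
#' @param config a [preprocess_config()].
#' @return The baseline-corrected [absorbance_spectrum()].
#' @export
baseline_correct <- function(spectrum, config = preprocess_config()) {
  bands <- config$baseline_anchor_bands
  nu <- axis_wavenumber(spectrum$axis)
  xm <- ym <- numeric(length(bands))
  for (i in seq_along(bands)) {
    idx <- band_points(spectrum$axis, bands[[i]])
    if (!length(idx))
      stop_argument(sprintf(
        "anchor band %.3g-%.3g um contains no grid points",
        bands[[i]][1], bands[[i]][2]))
    xm[i] <- mean(nu[idx]); ym[i] <- mean(spectrum$a[idx])
  }
  baseline <- if (length(bands) == 1) {
    rep(ym, length(nu))
  } else {
    co <- stats::lm.fit(cbind(1, xm), ym)$coefficients
    co[1] + co[2] * nu
  }
  absorbance_spectrum(spectrum$axis, spectrum$a - baseline,
                      reference = spectrum$reference,
                      n_reflections = spectrum$n_reflections)
}

#' Normalize to the O-H stretch peak
#'
#' Scales the spectrum so that its maximum inside the O-H window (default
#' 2.85--3.15 um) equals `reference_peak`.  Peak (not area) scaling is used;
#' normalizing replicate sessions to a common O-H peak removes contact and
#' throughput drift between measurements.
#'
#' @param spectrum an [absorbance_spectrum()].
#' @param reference_peak positive scalar the window maximum is mapped to.
#' @param config a [preprocess_config()].
#' @return The scaled [absorbance_spectrum()].
#' @export
normalize_oh <- function(spectrum, reference_peak,
                         config = preprocess_config()) {
  if (!is.finite(reference_peak) || reference_peak <= 0)
    stop_argument("reference_peak must be positive")
  idx <- band_points(spectrum$axis, config$oh_peak_window)
  if (!length(idx))
    stop_argument("oh_peak_window contains no grid points")
  m <- max(spectrum$a[idx])
  if (!is.finite(m) || m <= 0)
    stop_computation("non-positive maximum in the O-H window; cannot normalize")
  absorbance_spectrum(spectrum$axis, spectrum$a * (reference_peak / m),
                      reference = spectrum$reference,
                      n_reflections = spectrum$n_reflections)
}

#' Excise the atmospheric CO2 band
#'
#' Replaces values inside the CO2 window (default 4.20--4.35 um) by linear
#' interpolation in wavenumber between the nearest points just outside the
#' band; values outside are untouched.
#'
#' @param spectrum an [absorbance_spectrum()].
#' @param config a [preprocess_config()].
#' @return The corrected [absorbance_spectrum()].
#' @export
remove_co2 <- function(spectrum, config = preprocess_config()) {
  idx <- band_points(spectrum$axis, config$co2_band)
  if (!length(idx)) return(spectrum)
  n <- axis_length(spectrum$axis)
  if (1L %in% idx || n %in% idx)
    stop_argument("co2_band covers an endpoint of the axis; cannot bridge")
  nu <- axis_wavenumber(spectrum$axis)
  lo <- min(idx) - 1L; hi <- max(idx) + 1L
  a <- spectrum$a
  slope <- (a[hi] - a[lo]) / (nu[hi] - nu[lo])
  a[idx] <- a[lo] + slope * (nu[idx] - nu[lo])
  absorbance_spectrum(spectrum$axis, a, reference = spectrum$reference,
                      n_reflections = spectrum$n_reflections)
}

sg_kernel <- function(window, order) {
  f <- signal::sgolay(p = order, n = window)
  f[(window + 1L) / 2L, ]
}

# Core smoother on a uniform grid; first/last (window-1)/2 points are left
# unsmoothed so no data is fabricated at the band edges.
savgol_values <- function(y, window, order) {
  if (length(y) < window)
    stop_argument("spectrum shorter than the Savitzky-Golay window")
  kern <- sg_kernel(window, order)
  sm <- as.numeric(stats::filter(y, kern, sides = 2))
  half <- (window - 1L) / 2L
  sm[seq_len(half)] <- y[seq_len(half)]
  sm[seq(length(y) - half + 1L, length(y))] <-
    y[seq(length(y) - half + 1L, length(y))]
  sm
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay convolution (default window 5, cubic polynomial)
#' on a uniform grid.  Polynomials up to the filter order are preserved
#' exactly at interior points; the first and last `(window-1)/2` points are
#' left unsmoothed.  Non-uniform grids are refused: resample to an even
#' frequency grid first.
#'
#' @param spectrum an [absorbance_spectrum()] or [complex_index_spectrum()].
#' @param config a [preprocess_config()] supplying `sg_window`, `sg_order`.
#' @return The smoothed object, same class as the input.
#' @export
savgol_smooth <- function(spectrum, config = preprocess_config()) {
  vals <- spectrum$axis$values
  if (is.na(even_spacing(vals, tol = 1e-6)))
    stop_argument("Savitzky-Golay smoothing requires a uniform grid; ",
                  "resample to even frequency first")
  w <- config$sg_window; p <- config$sg_order
  if (inherits(spectrum, "absorbance_spectrum")) {
    absorbance_spectrum(spectrum$axis, savgol_values(spectrum$a, w, p),
                        reference = spectrum$reference,
                        n_reflections = spectrum$n_reflections)
  } else if (inherits(spectrum, "complex_index_spectrum")) {
    complex_index_spectrum(spectrum$axis,
                           savgol_values(spectrum$n, w, p),
                           savgol_values(spectrum$k, w, p),
                           differential = spectrum$differential,
                           valid = spectrum$valid)
  } else {
    stop_argument("unsupported object for savgol_smooth")
  }
}
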