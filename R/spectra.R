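#' Absorbance spectrum
#'
#' Decadic absorbance a = -log10(I/I0) on a spectral axis, tagged with the
#' reference used for I0 and the number of ATR reflections N.  Spectra
#' referenced to the purged atmosphere are absolute; spectra referenced to
#' water are differential (the solvent background has been divided out in
#' intensity, i.e. subtracted in absorbance).
#'
#' @param axis a [spectral_axis()].
#' @param a numeric absorbance, one value per axis point, all finite.
#' @param reference `"atmosphere"` (absolute) or `"water"` (differential).
#' @param n_reflections positive integer, the number of internal reflections
#'   N of the ATR element (10 for the reference instrument geometry).
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(axis, a, reference = c("atmosphere", "water"),
                                n_reflections = 10L) {
  reference <- match.arg(reference)
  stopifnot(inherits(axis, "spectral_axis"))
  a <- as.numeric(a)
  if (length(a) != axis_length(axis))
    stop_argument("absorbance length (", length(a),
                  ") does not match axis length (", axis_length(axis), ")")
  if (any(!is.finite(a)))
    stop_argument("absorbance values must all be finite")
  n_reflections <- as.integer(n_reflections)
  if (is.na(n_reflections) || n_reflections < 1)
    stop_argument("n_reflections must be a positive integer")
  structure(list(axis = axis, a = a, reference = reference,
                 n_reflections = n_reflections),
            class = "absorbance_spectrum")
}

#' Complex refractive index spectrum
#'
#' Paired real (n) and imaginary (k) refractive index on a spectral axis.
#' Absolute spectra must have k >= 0 everywhere (passivity); differential
#' spectra hold increments relative to a solvent and may take either sign.
#'
#' @param axis a [spectral_axis()].
#' @param n,k numeric vectors matching the axis length, all finite.
#' @param differential logical; `TRUE` marks an increment relative to water.
#' @param valid logical vector flagging points whose values are trustworthy;
#'   masked points (e.g. the short-wavelength calibration noise region)
#'   carry `FALSE` and are propagated, never silently filled.
#' @return An object of class `complex_index_spectrum`.
#' @export
complex_index_spectrum <- function(axis, n, k, differential = FALSE,
                                   valid = NULL) {
  stopifnot(inherits(axis, "spectral_axis"))
  n <- as.numeric(n); k <- as.numeric(k)
  len <- axis_length(axis)
  if (length(n) != len || length(k) != len)
    stop_argument("n and k must match the axis length")
  if (any(!is.finite(n)) || any(!is.finite(k)))
    stop_argument("n and k must be finite everywhere")
  if (!differential && any(k < 0))
    stop_argument("absolute spectra require k >= 0 everywhere")
  if (is.null(valid)) valid <- rep(TRUE, len)
  if (length(valid) != len)
    stop_argument("valid mask must match the axis length")
  structure(list(axis = axis, n = n, k = k,
                 differential = isTRUE(differential),
                 valid = as.logical(valid)),
            class = "complex_index_spectrum")
}

#' Imaginary-index spectrum
#'
#' The k(lambda) stage between the Beer-Lambert inversion and the
#' Kramers-Kronig step, with a validity mask inherited from the penetration
#' depth calibration.
#'
#' @inheritParams complex_index_spectrum
#' @return An object of class `k_spectrum`.
#' @export
k_spectrum <- function(axis, k, valid = NULL, differential = FALSE) {
  stopifnot(inherits(axis, "spectral_axis"))
  k <- as.numeric(k)
  len <- axis_length(axis)
  if (length(k) != len)
    stop_argument("k length must match the axis length")
  if (any(!is.finite(k)))
    stop_argument("k must be finite everywhere")
  if (!differential && any(k < 0))
    stop_argument("absolute k spectra must be non-negative")
  if (is.null(valid)) valid <- rep(TRUE, len)
  structure(list(axis = axis, k = k, valid = as.logical(valid),
                 differential = isTRUE(differential)),
            class = "k_spectrum")
}

#' Water optical-constants standard
#'
#' Literature (or synthetic ground-truth) real and imaginary refractive
#' index of the solvent, used (i) to calibrate the effective penetration
#' depth, (ii) to extrapolate k through the far-infrared (15--200 um) for
#' the Kramers-Kronig transform, and (iii) to anchor the index offset near
#' 2 um.  The table must therefore cover at least 1.67--200 um; queries
#' inside coverage are interpolated (monotone-safe piecewise cubic in
#' wavenumber) and queries outside coverage raise an error rather than
#' extrapolating.
#'
#' @param axis a [spectral_axis()] covering at least `coverage_um`.
#' @param n_ref,k_ref numeric index tables matching the axis, `k_ref >= 0`.
#' @param coverage_um required wavelength coverage in um.
#' @return An object of class `water_standard`.
#' @export
water_standard <- function(axis, n_ref, k_ref, coverage_um = c(1.67, 200)) {
  stopifnot(inherits(axis, "spectral_axis"))
  n_ref <- as.numeric(n_ref); k_ref <- as.numeric(k_ref)
  len <- axis_length(axis)
  if (length(n_ref) != len || length(k_ref) != len)
    stop_argument("n_ref and k_ref must match the axis length")
  if (any(!is.finite(n_ref)) || any(!is.finite(k_ref)) || any(k_ref < 0))
    stop_argument("standard tables must be finite with k_ref >= 0")
  wl <- axis_wavelength(axis)
  if (min(wl) > coverage_um[1] * (1 + 1e-6) ||
      max(wl) < coverage_um[2] * (1 - 1e-6))
    stop_argument(sprintf(
      "water standard must cover %.3g-%.4g um; got %.4g-%.5g um",
      coverage_um[1], coverage_um[2], min(wl), max(wl)))
  nu <- axis_wavenumber(axis)
  o <- order(nu)
  structure(list(nu = nu[o], n_ref = n_ref[o], k_ref = k_ref[o],
                 coverage_um = range(wl)),
            class = "water_standard")
}

# Monotone-safe piecewise-cubic interpolation on an ascending abscissa.
# Queries are clamped within a relative tolerance at the ends; anything
# further outside coverage is refused (no extrapolation).
interp_pchip <- function(x, y, xi, what = "interpolation") {
  lo <- x[1]; hi <- x[length(x)]
  tol <- 1e-9 * (hi - lo)
  if (any(xi < lo - tol) || any(xi > hi + tol))
    stop_argument(what, " query outside table coverage [",
                  format(lo), ", ", format(hi), "] cm^-1")
  xi <- pmin(pmax(xi, lo), hi)
  pracma::pchip(x, y, xi)
}

#' Interpolate a water standard at given wavelengths
#'
#' @param standard a [water_standard()].
#' @param wavelength_um query wavelengths in um, inside coverage.
#' @return Interpolated k (`standard_k`) or n (`standard_n`).
#' @export
standard_k <- function(standard, wavelength_um) {
  interp_pchip(standard$nu, standard$k_ref, 1e4 / wavelength_um,
               "water standard k")
}

#' @rdname standard_k
#' @export
standard_n <- function(standard, wavelength_um) {
  interp_pchip(standard$nu, standard$n_ref, 1e4 / wavelength_um,
               "water standard n")
}

#' Resample a spectrum onto an evenly spaced wavenumber grid
#'
#' The Kramers-Kronig quadrature requires data evenly spaced in frequency;
#' this resamples any monotone axis onto `n_points` equally spaced
#' wavenumbers spanning the input range, using monotone-safe piecewise-cubic
#' interpolation.  The input object is unchanged.
#'
#' @param spectrum an [absorbance_spectrum()] or [complex_index_spectrum()].
#' @param n_points number of output grid points (>= 2).
#' @return An object of the same class on the even grid.
#' @export
resample_even_frequency <- function(spectrum, n_points) {
  UseMethod("resample_even_frequency")
}

resample_grid <- function(axis, n_points) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2)
    stop_argument("n_points must be an integer >= 2")
  nu <- axis_wavenumber(axis)
  seq(min(nu), max(nu), length.out = n_points)
}

resample_values <- function(axis, y, nu_new) {
  nu <- axis_wavenumber(axis)
  if (nu[1] > nu[length(nu)]) { nu <- rev(nu); y <- rev(y) }
  interp_pchip(nu, y, nu_new, "resampling")
}

#' @export
resample_even_frequency.absorbance_spectrum <- function(spectrum, n_points) {
  nu_new <- resample_grid(spectrum$axis, n_points)
  absorbance_spectrum(spectral_axis(nu_new, "wavenumber"),
                      resample_values(spectrum$axis, spectrum$a, nu_new),
                      reference = spectrum$reference,
                      n_reflections = spectrum$n_reflections)
}

#' @export
resample_even_frequency.complex_index_spectrum <- function(spectrum,
                                                           n_points) {
  nu_new <- resample_grid(spectrum$axis, n_points)
  complex_index_spectrum(spectral_axis(nu_new, "wavenumber"),
                         resample_values(spectrum$axis, spectrum$n, nu_new),
                         resample_values(spectrum$axis, spectrum$k, nu_new),
                         differential = spectrum$differential)
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<absorbance_spectrum> %d points, reference=%s, N=%d, a in [%.4g, %.4g]\n",
    axis_length(x$axis), x$reference, x$n_reflections, min(x$a), max(x$a)))
  invisible(x)
}

#' @export
print.complex_index_spectrum <- function(x, ...) {
  cat(sprintf(
    "<complex_index_spectrum>%s %d points, n in [%.4g, %.4g], k in [%.4g, %.4g], %d masked\n",
    if (x$differential) " (differential)" else "", axis_length(x$axis),
    min(x$n), max(x$n), min(x$k), max(x$k), sum(!x$valid)))
  invisible(x)
}
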