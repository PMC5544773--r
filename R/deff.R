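LOG10E <- log10(exp(1))

#' Effective penetration depth curve
#'
#' Wavelength-dependent effective path length of the evanescent measurement,
#' stored as the total over all N reflections (so it scales down by N for a
#' single-reflection element).  Points where the calibration is unreliable
#' (short wavelengths where water absorbance and reference k are both near
#' zero, or reference k below the floor) carry an explicit invalid flag;
#' they are never replaced by zeros.
#'
#' @param axis a [spectral_axis()].
#' @param d_eff effective path length in um per point, `> 0` where valid.
#' @param valid logical validity mask.
#' @param n_reflections the reflection count N used during calibration.
#' @return An object of class `penetration_depth_curve`.
#' @export
penetration_depth_curve <- function(axis, d_eff, valid = NULL,
                                    n_reflections = 10L) {
  stopifnot(inherits(axis, "spectral_axis"))
  d_eff <- as.numeric(d_eff)
  len <- axis_length(axis)
  if (length(d_eff) != len)
    stop_argument("d_eff length must match the axis length")
  if (is.null(valid)) valid <- is.finite(d_eff) & d_eff > 0
  valid <- as.logical(valid) & is.finite(d_eff)
  if (any(valid & d_eff <= 0))
    stop_argument("d_eff must be positive wherever valid")
  structure(list(axis = axis, d_eff = d_eff, valid = valid,
                 n_reflections = as.integer(n_reflections)),
            class = "penetration_depth_curve")
}

#' Calibrate the effective penetration depth against a water standard
#'
#' For an uncollimated, unpolarised ATR beam the analytic single-angle
#' penetration-depth model cannot be evaluated, so the effective path is
#' determined empirically: rearranging the Beer-Lambert relation
#' k = lambda * a / (4 pi d log10 e) for d and inserting the measured water
#' absorbance together with the literature k of water gives
#'
#'   d_eff(lambda) = lambda * a_water(lambda) / (4 pi k_ref(lambda) log10 e)
#'
#' pointwise, absorbing the unknown angular spread, polarisation mix and
#' crystal dispersion into one measurable curve.  Points below the cutoff
#' wavelength (default 2.7 um), where both a and k_ref are approximately
#' zero and their ratio is noise, and points where `k_ref <= k_floor` are
#' masked invalid.
#'
#' @param a_water an [absorbance_spectrum()] of pure water referenced to
#'   atmosphere.
#' @param standard a [water_standard()].
#' @param cutoff_wavelength mask points with wavelength below this (um).
#' @param k_floor mask points where the standard k is at or below this.
#' @return A [penetration_depth_curve()] holding the total path (already
#'   times N).
#' @export
calibrate_deff <- function(a_water, standard, cutoff_wavelength = 2.7,
                           k_floor = 1e-4) {
  stopifnot(inherits(a_water, "absorbance_spectrum"))
  if (a_water$reference != "atmosphere")
    stop_argument("calibration needs an absolute (atmosphere-referenced) ",
                  "water spectrum")
  wl <- axis_wavelength(a_water$axis)
  k_ref <- standard_k(standard, wl)
  usable <- k_ref > k_floor
  d_eff <- rep(NA_real_, length(wl))
  d_eff[usable] <- wl[usable] * a_water$a[usable] /
    (4 * pi * k_ref[usable] * LOG10E)
  valid <- usable & wl >= cutoff_wavelength &
    is.finite(d_eff) & !is.na(d_eff) & d_eff > 0
  d_eff[is.na(d_eff)] <- 0
  if (!any(valid))
    stop_computation("all points masked during d_eff calibration")
  penetration_depth_curve(a_water$axis, d_eff, valid = valid,
                          n_reflections = a_water$n_reflections)
}

# d_eff (and its mask) interpolated onto a target axis.  Valid only where
# both bracketing calibration points are valid.
deff_on_axis <- function(deff, axis) {
  if (axes_equal(deff$axis, axis))
    return(list(d_eff = deff$d_eff, valid = deff$valid))
  nu_src <- axis_wavenumber(deff$axis)
  o <- order(nu_src)
  nu_q <- axis_wavenumber(axis)
  d <- interp_pchip(nu_src[o], deff$d_eff[o], nu_q, "d_eff")
  vsrc <- as.numeric(deff$valid[o])
  v <- stats::approx(nu_src[o], vsrc, xout = nu_q, rule = 2)$y >= 1 - 1e-9
  list(d_eff = d, valid = v & is.finite(d) & d > 0)
}

#' Imaginary index from absorbance (Beer-Lambert inversion)
#'
#' Evaluates k(lambda) = lambda * a(lambda) / (4 pi d_eff(lambda) log10 e)
#' at points where the penetration-depth calibration is valid; masked points
#' propagate as invalid.  Absolute spectra only -- a water-referenced
#' (differential) absorbance must go through the differential pathway,
#' where the same formula yields delta-k.
#'
#' @param a an [absorbance_spectrum()] referenced to atmosphere.
#' @param deff a [penetration_depth_curve()] from [calibrate_deff()].
#' @return A [k_spectrum()].
#' @export
k_from_absorbance <- function(a, deff) {
  stopifnot(inherits(a, "absorbance_spectrum"),
            inherits(deff, "penetration_depth_curve"))
  if (a$reference == "water")
    stop_argument("water-referenced absorbance is differential; ",
                  "use extract_differential()")
  if (a$n_reflections != deff$n_reflections)
    stop_argument("spectrum N (", a$n_reflections,
                  ") differs from calibration N (", deff$n_reflections, ")")
  d <- deff_on_axis(deff, a$axis)
  wl <- axis_wavelength(a$axis)
  k <- rep(0, length(wl))
  ok <- d$valid
  k[ok] <- wl[ok] * a$a[ok] / (4 * pi * d$d_eff[ok] * LOG10E)
  k[k < 0 & ok] <- 0
  k_spectrum(a$axis, k, valid = ok, differential = FALSE)
}

#' Forward Beer-Lambert absorbance from k (inverse of [k_from_absorbance()])
#'
#' @param k a [k_spectrum()] or [complex_index_spectrum()].
#' @param deff a [penetration_depth_curve()].
#' @return An [absorbance_spectrum()] with
#'   a = 4 pi d_eff k log10 e / lambda at valid points (0 where masked).
#' @export
absorbance_from_k <- function(k, deff) {
  stopifnot(inherits(deff, "penetration_depth_curve"))
  axis <- k$axis
  d <- deff_on_axis(deff, axis)
  wl <- axis_wavelength(axis)
  a <- rep(0, length(wl))
  ok <- d$valid
  a[ok] <- 4 * pi * d$d_eff[ok] * k$k[ok] * LOG10E / wl[ok]
  absorbance_spectrum(axis, a, reference = "atmosphere",
                      n_reflections = deff$n_reflections)
}

#' @export
print.penetration_depth_curve <- function(x, ...) {
  cat(sprintf(
    "<penetration_depth_curve> %d points, N=%d, %d valid, d_eff in [%.4g, %.4g] um\n",
    axis_length(x$axis), x$n_reflections, sum(x$valid),
    min(x$d_eff[x$valid]), max(x$d_eff[x$valid])))
  invisible(x)
}
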