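#' Spectral axis
#'
#' An ordered grid of spectral positions with a declared unit, either
#' wavenumber (cm^-1) or vacuum wavelength (um).  The two views are related
#' pointwise by lambda\[um\] = 1e4 / nu\[cm^-1\], so converting reverses the
#' monotonicity direction and converting twice returns the original values.
#'
#' @param values numeric vector of spectral positions, strictly monotone
#'   (either direction), all positive, length >= 2.
#' @param unit `"wavenumber"` (cm^-1) or `"wavelength"` (um).
#' @return An object of class `spectral_axis`.
#' @examples
#' ax <- spectral_axis(seq(600, 6000, by = 4), "wavenumber")
#' range(axis_wavelength(ax))   # 1.67 -- 16.7 um
#' @export
spectral_axis <- function(values, unit = c("wavenumber", "wavelength")) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2)
    stop_argument("a spectral axis needs at least 2 points")
  if (any(!is.finite(values)))
    stop_argument("spectral axis values must all be finite")
  if (any(values <= 0))
    stop_argument("spectral positions must be strictly positive")
  d <- diff(values)
  if (!(all(d > 0) || all(d < 0)))
    stop_argument("spectral axis values must be strictly monotone")
  structure(list(values = values, unit = unit), class = "spectral_axis")
}

#' Convert a spectral axis between wavenumber and wavelength
#'
#' Applies lambda\[um\] = 1e4 / nu\[cm^-1\] pointwise (and the identical map in
#' the other direction).  The conversion is an involution: converting twice
#' recovers the original values to machine precision.
#'
#' @param axis a [spectral_axis()].
#' @param target_unit `"wavenumber"` or `"wavelength"`.
#' @return A `spectral_axis` in the target unit.
#' @export
convert_axis <- function(axis, target_unit = c("wavenumber", "wavelength")) {
  target_unit <- match.arg(target_unit)
  stopifnot(inherits(axis, "spectral_axis"))
  if (axis$unit == target_unit) return(axis)
  spectral_axis(1e4 / axis$values, target_unit)
}

#' @rdname spectral_axis
#' @export
axis_wavelength <- function(axis) {
  if (axis$unit == "wavelength") axis$values else 1e4 / axis$values
}

#' @rdname spectral_axis
#' @export
axis_wavenumber <- function(axis) {
  if (axis$unit == "wavenumber") axis$values else 1e4 / axis$values
}

axis_length <- function(axis) length(axis$values)

# Relative tolerance for "same grid" checks; file round trips keep 12
# significant digits so 1e-9 separates real mismatches from format noise.
AXIS_TOL <- 1e-9

axes_equal <- function(a, b, tol = AXIS_TOL) {
  if (axis_length(a) != axis_length(b)) return(FALSE)
  va <- axis_wavenumber(a)
  vb <- axis_wavenumber(b)
  if (va[1] > va[length(va)]) va <- rev(va)
  if (vb[1] > vb[length(vb)]) vb <- rev(vb)
  all(abs(va - vb) <= tol * pmax(abs(va), abs(vb)))
}

# Spacing of an evenly spaced wavenumber grid, or NA if the grid is uneven.
even_spacing <- function(nu, tol = 1e-8) {
  h <- (nu[length(nu)] - nu[1]) / (length(nu) - 1)
  if (any(abs(diff(nu) - h) > tol * abs(h))) return(NA_real_)
  h
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %s, %.6g to %.6g\n",
              length(x$values), x$unit, x$values[1],
              x$values[length(x$values)]))
  invisible(x)
}
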