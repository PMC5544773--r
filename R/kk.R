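#' Extension and offset configuration for the Kramers-Kronig step
#'
#' The Kramers-Kronig integral formally runs over all frequencies, so the
#' band-limited measured k must be extended before transforming.  Below the
#' measured band, k is spliced onto the water standard through the
#' far-infrared (default 15--200 um), since water absorption dominates all
#' common aqueous samples there; above the band, k is extended as zero up
#' to `high_factor` times the maximum measured wavenumber (the high side
#' carries no significant features).  The transform returns the real part
#' only up to an additive constant, which is fixed by anchoring to the
#' standard's n at a low-loss wavelength near 2 um.
#'
#' @param low_band_um `c(lo, hi)` wavelength interval (um) over which the
#'   standard's k replaces/extends the measurement; `lo` is the splice
#'   point, `hi` the far-infrared limit of the extension.
#' @param junction_um `c(lo, hi)` wavelength window over which measured and
#'   standard k are linearly cross-faded (avoids a step that would ring
#'   through the principal-value sum).
#' @param anchor_um wavelength (um) at which the offset is fixed.
#' @param anchor_window_um optional `c(lo, hi)`; when given, the offset
#'   matches window means instead of a single point.
#' @param high_extension `"zero"` to pad zeros above the band, `"none"`.
#' @param high_factor upper grid limit as a multiple of the maximum
#'   measured wavenumber (used when `high_extension = "zero"`).
#' @return An object of class `extension_config`.
#' @export
extension_config <- function(low_band_um = c(15, 200),
                             junction_um = c(14, 15),
                             anchor_um = 2.0,
                             anchor_window_um = NULL,
                             high_extension = c("zero", "none"),
                             high_factor = 2) {
  high_extension <- match.arg(high_extension)
  if (length(low_band_um) != 2 || low_band_um[1] >= low_band_um[2])
    stop_argument("low_band_um must be c(lo, hi) with lo < hi")
  if (length(junction_um) != 2 || junction_um[1] >= junction_um[2])
    stop_argument("junction_um must be c(lo, hi) with lo < hi")
  if (high_factor <= 1)
    stop_argument("high_factor must exceed 1")
  structure(list(low_band_um = low_band_um, junction_um = junction_um,
                 anchor_um = anchor_um, anchor_window_um = anchor_window_um,
                 high_extension = high_extension, high_factor = high_factor),
            class = "extension_config")
}

#' Extend a measured k spectrum with the water standard
#'
#' Builds a single evenly spaced wavenumber grid running from the
#' far-infrared limit of `config$low_band_um` up through the measured band
#' (plus the optional zero-padded high side), at the measured grid spacing.
#' On it, k equals the standard inside the low band, the measurement inside
#' the measured band, with a linear cross-fade over `config$junction_um`.
#' Masked (invalid) measured points are substituted with the standard's k
#' -- never zeros -- since the transform needs a physical integrand there.
#'
#' With `standard = NULL` (the differential pathway) no values are added:
#' the increment delta-k is taken as zero outside the measured band, and
#' zero integrand contributes nothing to the principal-value sum.
#'
#' @param k_measured a [k_spectrum()] on an even wavenumber grid.
#' @param standard a [water_standard()], or `NULL` for zero extension.
#' @param config an [extension_config()].
#' @return An object of class `extended_k`: fields `frequency` (cm^-1,
#'   ascending, even), `chi2` (the extended imaginary part) and
#'   `measured_range`.
#' @export
extend_with_standard <- function(k_measured, standard,
                                 config = extension_config()) {
  stopifnot(inherits(k_measured, "k_spectrum"))
  nu <- axis_wavenumber(k_measured$axis)
  k <- k_measured$k
  valid <- k_measured$valid
  if (nu[1] > nu[length(nu)]) { nu <- rev(nu); k <- rev(k); valid <- rev(valid) }
  h <- even_spacing(nu)
  if (is.na(h))
    stop_argument("k must be on an evenly spaced wavenumber grid; ",
                  "resample_even_frequency() first")
  wl <- 1e4 / nu

  if (is.null(standard)) {
    k[!valid] <- 0
    out <- list(frequency = nu, chi2 = k,
                measured_range = c(nu[1], nu[length(nu)]))
    class(out) <- "extended_k"
    return(out)
  }

  cov_nu <- range(standard$nu)
  nu_far <- 1e4 / config$low_band_um[2]    # far-infrared grid limit
  nu_splice <- 1e4 / config$low_band_um[1] # standard used below this
  if (cov_nu[1] > nu_far * (1 + 1e-9) || cov_nu[2] < min(nu_splice, nu[1]))
    stop_argument("water standard does not cover the low-frequency ",
                  "extension band; gap not coverable")

  meas_lo <- nu[1]; meas_hi <- nu[length(nu)]

  # inside the measured band: substitute standard k at masked points,
  # replace by the standard below the splice, cross-fade over the junction
  if (any(!valid)) k[!valid] <- standard_k(standard, wl[!valid])
  k_std_band <- interp_pchip(standard$nu, standard$k_ref, nu, "standard k")
  nu_j1 <- 1e4 / config$junction_um[2]
  nu_j2 <- 1e4 / config$junction_um[1]
  w <- pmin(pmax((nu - nu_j1) / (nu_j2 - nu_j1), 0), 1)
  k <- w * k + (1 - w) * k_std_band

  # low-frequency extension on the same spacing
  n_low <- floor((nu[1] - nu_far) / h + 1e-9)
  if (n_low > 0) {
    nu_low <- nu[1] - h * rev(seq_len(n_low))
    k_low <- interp_pchip(standard$nu, standard$k_ref, nu_low, "standard k")
    nu <- c(nu_low, nu); k <- c(k_low, k)
  }

  # zero-padded high side
  if (config$high_extension == "zero") {
    n_high <- floor((config$high_factor - 1) * meas_hi / h)
    if (n_high > 0) {
      nu <- c(nu, meas_hi + h * seq_len(n_high))
      k <- c(k, rep(0, n_high))
    }
  }
  structure(list(frequency = nu, chi2 = pmax(k, 0),
                 measured_range = c(meas_lo, meas_hi)),
            class = "extended_k")
}

#' Kramers-Kronig transform: real part from imaginary part
#'
#' Computes the causality relation
#' chi1(omega) = (2/pi) P \\int_0^Inf omega' chi2(omega') /
#' (omega'^2 - omega^2) d omega' (the positive-frequency form of the
#' principal-value Hilbert pair, using the odd symmetry of chi2) on an
#' evenly spaced frequency grid by Maclaurin's formula: at each output
#' point the integrand is sampled at the grid points of opposite parity,
#' with spacing 2h, so the singular point is never evaluated.  The scheme
#' is the standard one for band-limited optical constants; applied to k it
#' returns n up to the additive constant fixed by [offset_to_anchor()].
#'
#' @param frequency evenly spaced, ascending, positive frequencies (cm^-1).
#' @param chi2 imaginary part sampled on `frequency`.
#' @return `chi1`, the transform evaluated at every grid point.
#' @export
kk_real_from_imag <- function(frequency, chi2) {
  frequency <- as.numeric(frequency); chi2 <- as.numeric(chi2)
  n <- length(frequency)
  if (n < 4 || length(chi2) != n)
    stop_argument("frequency and chi2 must have equal length >= 4")
  if (any(!is.finite(frequency)) || any(!is.finite(chi2)))
    stop_argument("frequency and chi2 must be finite")
  h <- even_spacing(frequency)
  if (is.na(h) || h <= 0)
    stop_argument("the grid must be evenly spaced and ascending in frequency")
  w <- frequency
  g <- w * chi2
  odd <- seq(1L, n, 2L)
  even <- seq(2L, n, 2L)
  chi1 <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i %% 2L == 0L) odd else even
    chi1[i] <- sum(g[j] / ((w[j] - w[i]) * (w[j] + w[i])))
  }
  (4 * h / pi) * chi1
}

#' Anchor the Kramers-Kronig result to the standard's index
#'
#' The transform returns the real index only up to a wavelength-independent
#' constant.  The constant is fixed by matching the standard's n at a
#' low-loss anchor wavelength (default 2 um) where no depolarisation
#' mechanism of the dissolved analytes contributes:
#' `c = n_ref(anchor) - n_raw(anchor)` is added everywhere, so the output
#' equals the standard exactly at the anchor while all differences between
#' wavelengths are preserved.
#'
#' @param n_raw a [complex_index_spectrum()] whose `n` is determined up to
#'   an additive constant.
#' @param standard a [water_standard()].
#' @param config an [extension_config()] providing the anchor.
#' @return The shifted [complex_index_spectrum()].
#' @export
offset_to_anchor <- function(n_raw, standard, config = extension_config()) {
  stopifnot(inherits(n_raw, "complex_index_spectrum"))
  nu <- axis_wavenumber(n_raw$axis)
  o <- order(nu)
  win <- config$anchor_window_um
  if (is.null(win)) {
    anchor_nu <- 1e4 / config$anchor_um
    if (anchor_nu < min(nu) || anchor_nu > max(nu))
      stop_argument("anchor wavelength lies outside the spectrum band")
    n_at <- interp_pchip(nu[o], n_raw$n[o], anchor_nu, "anchor")
    n_ref_at <- standard_n(standard, config$anchor_um)
  } else {
    wl <- 1e4 / nu
    idx <- which(wl >= win[1] & wl <= win[2])
    if (!length(idx))
      stop_argument("anchor window contains no grid points")
    n_at <- mean(n_raw$n[idx])
    n_ref_at <- mean(standard_n(standard, wl[idx]))
  }
  complex_index_spectrum(n_raw$axis, n_raw$n + (n_ref_at - n_at), n_raw$k,
                         differential = n_raw$differential,
                         valid = n_raw$valid)
}

#' Full k -> n chain: extend, transform, crop, anchor
#'
#' Convenience wrapper running [extend_with_standard()],
#' [kk_real_from_imag()] and (for absolute spectra) [offset_to_anchor()],
#' returning the complex index on the measured band.  With
#' `standard = NULL` the result is the differential increment: zero
#' low-frequency extension and no offset, since the solvent background has
#' already been removed by the water-referenced measurement.
#'
#' @param k_measured a [k_spectrum()] on an even wavenumber grid.
#' @param standard a [water_standard()] or `NULL` (differential).
#' @param config an [extension_config()].
#' @param extend set `FALSE` to transform the bare measured band without
#'   any extension (used to demonstrate the long-wavelength divergence).
#' @return A [complex_index_spectrum()] on the measured grid.
#' @export
kk_n_from_k <- function(k_measured, standard = NULL,
                        config = extension_config(), extend = TRUE) {
  if (extend) {
    ext <- extend_with_standard(k_measured, standard, config)
  } else {
    nu0 <- axis_wavenumber(k_measured$axis)
    k0 <- k_measured$k
    v0 <- k_measured$valid
    if (nu0[1] > nu0[length(nu0)]) { nu0 <- rev(nu0); k0 <- rev(k0); v0 <- rev(v0) }
    if (!is.null(standard) && any(!v0))
      k0[!v0] <- standard_k(standard, 1e4 / nu0[!v0])
    if (is.null(standard)) k0[!v0] <- 0
    ext <- structure(list(frequency = nu0, chi2 = k0,
                          measured_range = c(nu0[1], nu0[length(nu0)])),
                     class = "extended_k")
  }
  chi1 <- kk_real_from_imag(ext$frequency, ext$chi2)
  tol <- 1e-6 * diff(ext$measured_range)
  idx <- which(ext$frequency >= ext$measured_range[1] - tol &
               ext$frequency <= ext$measured_range[2] + tol)
  axis <- spectral_axis(ext$frequency[idx], "wavenumber")
  # carry the measurement's k and validity mask back onto the cropped grid:
  # the junction fade and masked-point substitution feed the transform
  # integrand only, the reported k stays the measurement's own (with the
  # standard substituted at masked points, flagged invalid)
  nu_meas <- axis_wavenumber(k_measured$axis)
  om <- order(nu_meas)
  vmask <- stats::approx(nu_meas[om], as.numeric(k_measured$valid[om]),
                         xout = ext$frequency[idx], rule = 2)$y >= 1 - 1e-9
  k_out <- k_measured$k[om]
  if (any(!k_measured$valid[om])) {
    bad <- !k_measured$valid[om]
    k_out[bad] <- if (is.null(standard)) 0 else
      standard_k(standard, 1e4 / nu_meas[om][bad])
  }
  k_out <- stats::approx(nu_meas[om], k_out, xout = ext$frequency[idx])$y
  differential <- is.null(standard)
  ci <- complex_index_spectrum(axis, chi1[idx],
                               if (differential) k_out else pmax(k_out, 0),
                               differential = differential, valid = vmask)
  if (!differential) ci <- offset_to_anchor(ci, standard, config)
  ci
}
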