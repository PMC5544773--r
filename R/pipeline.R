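extraction_result <- function(absolute = NULL, differential = NULL,
                              deff_used = NULL, provenance = list()) {
  structure(list(absolute = absolute, differential = differential,
                 deff_used = deff_used, provenance = provenance),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result>\n")
  if (!is.null(x$absolute)) { cat("  absolute: "); print(x$absolute) }
  if (!is.null(x$differential)) {
    cat("  differential: "); print(x$differential)
  }
  if (!is.null(x$deff_used)) { cat("  deff_used: "); print(x$deff_used) }
  invisible(x)
}

preprocess_chain <- function(spectrum, reference_peak, config) {
  s <- baseline_correct(spectrum, config)
  s <- normalize_oh(s, reference_peak, config)
  remove_co2(s, config)
}

#' Absolute complex-index extraction
#'
#' The full end-to-end chain for a sample measured against the purged
#' atmosphere: condition both sample and water spectra (baseline, common
#' O-H normalization, CO2 excision), resample to an even wavenumber grid,
#' calibrate the effective penetration depth from the water measurement and
#' the standard, invert Beer-Lambert for k, then extend / Kramers-Kronig
#' transform / offset-anchor for n.  The short-wavelength mask from the
#' calibration is propagated into the result, never filled silently.
#'
#' @param sample_abs sample [absorbance_spectrum()] (or list of replicates)
#'   referenced to atmosphere.
#' @param water_abs water [absorbance_spectrum()] (or list of replicates),
#'   same axis and N as the sample.
#' @param standard a [water_standard()].
#' @param preprocess_cfg a [preprocess_config()], or `NULL` to skip the
#'   conditioning chain (already-conditioned or synthetic input).
#' @param extension_cfg an [extension_config()].
#' @param cutoff_wavelength short-wavelength validity cutoff (um) for the
#'   calibration.
#' @return An `extraction_result` with fields `absolute`
#'   (a [complex_index_spectrum()]), `deff_used` and `provenance`.
#' @export
extract_absolute <- function(sample_abs, water_abs, standard,
                             preprocess_cfg = preprocess_config(),
                             extension_cfg = extension_config(),
                             cutoff_wavelength = 2.7) {
  sample_abs <- average_replicates(sample_abs)
  water_abs <- average_replicates(water_abs)
  if (sample_abs$reference != "atmosphere" ||
      water_abs$reference != "atmosphere")
    stop_argument("absolute extraction needs atmosphere-referenced spectra")
  if (sample_abs$n_reflections != water_abs$n_reflections)
    stop_argument("sample and water must share the same reflection count N")
  if (!axes_equal(sample_abs$axis, water_abs$axis))
    stop_argument("sample and water must share the same axis")
  wl <- axis_wavelength(sample_abs$axis)
  if (min(wl) > standard$coverage_um[2] || max(wl) < standard$coverage_um[1])
    stop_argument("sample axis does not overlap the water standard coverage")

  if (!is.null(preprocess_cfg)) {
    water_bl <- baseline_correct(water_abs, preprocess_cfg)
    oh_idx <- band_points(water_bl$axis, preprocess_cfg$oh_peak_window)
    if (!length(oh_idx))
      stop_argument("oh_peak_window contains no grid points")
    ref_peak <- max(water_bl$a[oh_idx])
    if (ref_peak <= 0)
      stop_computation("water O-H window maximum is non-positive")
    water_abs <- remove_co2(normalize_oh(water_bl, ref_peak, preprocess_cfg),
                            preprocess_cfg)
    sample_abs <- preprocess_chain(sample_abs, ref_peak, preprocess_cfg)
  }

  n_pts <- axis_length(sample_abs$axis)
  sample_abs <- resample_even_frequency(sample_abs, n_pts)
  water_abs <- resample_even_frequency(water_abs, n_pts)

  deff <- calibrate_deff(water_abs, standard,
                         cutoff_wavelength = cutoff_wavelength)
  ks <- k_from_absorbance(sample_abs, deff)
  ci <- kk_n_from_k(ks, standard, extension_cfg)
  extraction_result(
    absolute = ci, deff_used = deff,
    provenance = list(paths = "absolute",
                      preprocess = preprocess_cfg,
                      extension = extension_cfg,
                      cutoff_wavelength = cutoff_wavelength,
                      n_reflections = sample_abs$n_reflections,
                      package_version =
                        as.character(utils::packageVersion("atrindex"))))
}

#' Differential complex-index extraction
#'
#' For a solution measured directly against a DI-water reference the
#' absorbance is differential: the solvent background has been removed by
#' the measurement itself.  The same water-calibrated effective penetration
#' depth applies unchanged (water still dominates the evanescent field), so
#' delta-k = lambda a_diff / (4 pi d_eff log10 e), and delta-n follows from
#' the Kramers-Kronig transform of delta-k with zero extension outside the
#' band and no offset step.  Savitzky-Golay smoothing (window 5, cubic) is
#' applied last to both outputs.
#'
#' @param diff_abs a water-referenced [absorbance_spectrum()] (or replicate
#'   list).
#' @param deff a [penetration_depth_curve()] from [calibrate_deff()].
#' @param extension_cfg an [extension_config()].
#' @param sg_cfg a [preprocess_config()] supplying the smoothing window.
#' @param smooth logical; set `FALSE` to skip the smoothing step.
#' @return An `extraction_result` with field `differential`, a
#'   [complex_index_spectrum()] holding (delta-n, delta-k) flagged
#'   differential.
#' @export
extract_differential <- function(diff_abs, deff,
                                 extension_cfg = extension_config(),
                                 sg_cfg = preprocess_config(),
                                 smooth = TRUE) {
  diff_abs <- average_replicates(diff_abs)
  if (diff_abs$reference != "water")
    stop_argument("differential extraction needs a water-referenced ",
                  "spectrum; use extract_absolute() for absolute spectra")
  stopifnot(inherits(deff, "penetration_depth_curve"))
  diff_abs <- resample_even_frequency(diff_abs, axis_length(diff_abs$axis))
  d <- deff_on_axis(deff, diff_abs$axis)
  wl <- axis_wavelength(diff_abs$axis)
  dk <- rep(0, length(wl))
  ok <- d$valid
  dk[ok] <- wl[ok] * diff_abs$a[ok] / (4 * pi * d$d_eff[ok] * LOG10E)
  kdiff <- k_spectrum(diff_abs$axis, dk, valid = ok, differential = TRUE)
  ci <- kk_n_from_k(kdiff, standard = NULL, config = extension_cfg)
  if (smooth) ci <- savgol_smooth(ci, sg_cfg)
  extraction_result(
    differential = ci, deff_used = deff,
    provenance = list(paths = "differential",
                      extension = extension_cfg, sg = sg_cfg,
                      smooth = smooth,
                      package_version =
                        as.character(utils::packageVersion("atrindex"))))
}

#' Subtract two complex index spectra
#'
#' Pointwise difference (n_a - n_b, k_a - k_b) on a common axis, flagged
#' differential -- the large-perturbation route to an analyte's index
#' increment (e.g. whole blood minus water).
#'
#' @param a,b [complex_index_spectrum()] objects on the same axis.
#' @return A differential [complex_index_spectrum()].
#' @export
subtract_index <- function(a, b) {
  stopifnot(inherits(a, "complex_index_spectrum"),
            inherits(b, "complex_index_spectrum"))
  if (!axes_equal(a$axis, b$axis))
    stop_argument("index spectra must share a common axis")
  complex_index_spectrum(a$axis, a$n - b$n, a$k - b$k,
                         differential = TRUE, valid = a$valid & b$valid)
}

#' Water self-consistency check of the Kramers-Kronig chain
#'
#' Runs extend -> transform -> offset on the water standard's own k sampled
#' over the measurement band and compares the recovered n with the
#' standard's n table, reporting the maximum absolute error over
#' `compare_um` and the long-wavelength divergence of the unextended
#' transform (deviation at the longest wavelength relative to its mean near
#' the 2 um anchor).
#'
#' @param standard a [water_standard()].
#' @param band_um measurement band in um.
#' @param step_cm1 grid step of the check (cm^-1).
#' @param config an [extension_config()].
#' @param compare_um wavelength window for the error statistic.
#' @return A list: `max_abs_error`, `divergence_ratio`,
#'   `dev_long`, `dev_anchor`, `n_points`, plus the recovered spectra.
#' @export
water_selfcheck <- function(standard, band_um = c(1.67, 16.7),
                            step_cm1 = 4, config = extension_config(),
                            compare_um = c(2, 15)) {
  nu <- seq(ceiling(1e4 / band_um[2] / step_cm1) * step_cm1,
            floor(1e4 / band_um[1] / step_cm1) * step_cm1,
            by = step_cm1)
  axis <- spectral_axis(nu, "wavenumber")
  wl <- axis_wavelength(axis)
  k_meas <- k_spectrum(axis, standard_k(standard, wl))
  ci_ext <- kk_n_from_k(k_meas, standard, config, extend = TRUE)
  ci_noext <- kk_n_from_k(k_meas, standard, config, extend = FALSE)
  n_ref <- standard_n(standard, wl)
  in_cmp <- wl >= compare_um[1] & wl <= compare_um[2]
  max_abs_error <- max(abs(ci_ext$n[in_cmp] - n_ref[in_cmp]))
  dev <- abs(ci_noext$n - ci_ext$n)
  anchor_win <- config$anchor_um * c(0.95, 1.05)
  near_anchor <- wl >= anchor_win[1] & wl <= anchor_win[2]
  dev_anchor <- mean(dev[near_anchor])
  dev_long <- dev[which.max(wl)]
  list(max_abs_error = max_abs_error,
       divergence_ratio = dev_long / dev_anchor,
       dev_long = dev_long, dev_anchor = dev_anchor,
       n_points = length(nu),
       recovered = ci_ext, unextended = ci_noext, n_ref = n_ref,
       wavelength_um = wl)
}
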