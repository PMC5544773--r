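#' Lorentz oscillator model of the complex dielectric function
#'
#' eps(omega) = eps_inf + sum_j S_j / (omega0_j^2 - omega^2 - i gamma_j
#' omega), the causal damped-resonance susceptibility whose real and
#' imaginary parts are an exact Kramers-Kronig pair.  Used as analytic
#' ground truth for the calibration, transform and differential stages:
#' every spectrum generated from it is causal by construction.
#'
#' @param eps_inf high-frequency dielectric constant (>= 1).
#' @param centers oscillator centre wavenumbers omega0 (cm^-1).
#' @param strengths oscillator strengths S (cm^-2), all `>= 0`.
#' @param gammas damping linewidths gamma (cm^-1), all `> 0`.
#' @return An object of class `lorentz_model`.
#' @export
lorentz_model <- function(eps_inf, centers = numeric(), strengths = numeric(),
                          gammas = numeric()) {
  if (!is.finite(eps_inf) || eps_inf < 1)
    stop_argument("eps_inf must be finite and >= 1")
  if (length(centers) != length(strengths) ||
      length(centers) != length(gammas))
    stop_argument("centers, strengths and gammas must have equal length")
  if (any(strengths < 0)) stop_argument("oscillator strengths must be >= 0")
  if (length(gammas) && any(gammas <= 0))
    stop_argument("oscillator dampings must be > 0")
  structure(list(eps_inf = eps_inf, centers = as.numeric(centers),
                 strengths = as.numeric(strengths),
                 gammas = as.numeric(gammas)),
            class = "lorentz_model")
}

#' Add oscillators to a Lorentz model
#'
#' @param model a [lorentz_model()].
#' @param centers,strengths,gammas parameters of the added oscillators.
#' @return The augmented [lorentz_model()].
#' @export
add_oscillators <- function(model, centers, strengths, gammas) {
  lorentz_model(model$eps_inf, c(model$centers, centers),
                c(model$strengths, strengths), c(model$gammas, gammas))
}

# Complex dielectric function at wavenumbers nu (cm^-1).
model_epsilon <- function(model, nu) {
  eps <- complex(real = rep(model$eps_inf, length(nu)), imaginary = 0)
  for (j in seq_along(model$centers)) {
    eps <- eps + model$strengths[j] /
      (model$centers[j]^2 - nu^2 -
         complex(real = 0, imaginary = 1) * model$gammas[j] * nu)
  }
  eps
}

#' Closed-form susceptibility of a Lorentz model
#'
#' Real and imaginary parts of eps(omega) - eps_inf, the analytic
#' Kramers-Kronig pair used as the oracle for the numerical transform.
#'
#' @param model a [lorentz_model()].
#' @param nu wavenumbers (cm^-1).
#' @return A list with `chi1` and `chi2`.
#' @export
model_susceptibility <- function(model, nu) {
  eps <- model_epsilon(model, nu)
  list(chi1 = Re(eps) - model$eps_inf, chi2 = Im(eps))
}

#' Complex refractive index of a Lorentz model
#'
#' n + ik = sqrt(eps) with the branch giving n > 0, k >= 0.
#'
#' @param model a [lorentz_model()].
#' @param axis a [spectral_axis()].
#' @return A [complex_index_spectrum()].
#' @export
model_complex_index <- function(model, axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  nu <- axis_wavenumber(axis)
  N <- sqrt(model_epsilon(model, nu))
  N <- ifelse(Re(N) < 0, -N, N)  # principal branch with n > 0
  k <- Im(N)
  if (any(k < -1e-12))
    stop_argument("model parameters produce k < 0")
  complex_index_spectrum(axis, Re(N), pmax(k, 0))
}

#' ATR element and beam configuration for the forward simulator
#'
#' @param crystal_index real refractive index of the ATR element (a ZnSe
#'   element is close to 2.4 across the mid-infrared).
#' @param angle_deg nominal internal angle of incidence in degrees.
#' @param angle_spread `"delta"` (collimated), `"uniform"` (half-width
#'   `spread_deg` about the nominal angle) or `"gaussian"` (sigma
#'   `spread_deg`, truncated at 3 sigma) -- hypotheses for the uncollimated
#'   beam of a transmission-optimised spectrometer.
#' @param spread_deg half-width or sigma of the angular distribution.
#' @param te_fraction TE (s-polarised) power fraction in \[0, 1\];
#'   0.5 is unpolarised.
#' @param n_reflections number of internal reflections N.
#' @return An object of class `atr_config`.
#' @export
atr_config <- function(crystal_index = 2.4, angle_deg = 45,
                       angle_spread = c("delta", "uniform", "gaussian"),
                       spread_deg = 0, te_fraction = 0.5,
                       n_reflections = 10L) {
  angle_spread <- match.arg(angle_spread)
  if (te_fraction < 0 || te_fraction > 1)
    stop_argument("te_fraction must lie in [0, 1]")
  if (angle_spread != "delta" && spread_deg <= 0)
    stop_argument("spread_deg must be > 0 for a non-delta distribution")
  structure(list(crystal_index = crystal_index, angle_deg = angle_deg,
                 angle_spread = angle_spread, spread_deg = spread_deg,
                 te_fraction = te_fraction,
                 n_reflections = as.integer(n_reflections)),
            class = "atr_config")
}

#' Single-reflection evanescent penetration depth
#'
#' d_p = lambda / (2 pi n1 sqrt(sin^2 theta - n21^2)) with n21 = n2/n1,
#' the decay length of the evanescent field below the crystal/sample
#' interface.  Defined only above the critical angle.
#'
#' @param lambda_um wavelength in um.
#' @param angle_deg internal angle of incidence in degrees.
#' @param n1 crystal index.
#' @param n2 sample (real) index.
#' @return Penetration depth in um.
#' @export
harrick_penetration_depth <- function(lambda_um, angle_deg, n1, n2) {
  th <- angle_deg * pi / 180
  disc <- sin(th)^2 - (n2 / n1)^2
  if (any(disc <= 0))
    stop_computation("angle at or below the critical angle: ",
                     "no evanescent field")
  lambda_um / (2 * pi * n1 * sqrt(disc))
}

#' Weak-absorption effective thickness of a single ATR reflection
#'
#' The standard single-reflection effective-thickness expressions for weak
#' absorption: the sample thickness that would give the same absorbance in
#' transmission as one evanescent reflection, per polarisation
#' (lambda1 = lambda/n1, n21 = n2/n1, theta the internal angle):
#'
#'   d_e(TE) = n21 lambda1 cos(theta) / (pi (1 - n21^2)
#'             sqrt(sin^2 theta - n21^2))
#'
#'   d_e(TM) = n21 lambda1 cos(theta) (2 sin^2 theta - n21^2) /
#'             (pi (1 - n21^2) ((1 + n21^2) sin^2 theta - n21^2)
#'             sqrt(sin^2 theta - n21^2))
#'
#' An unpolarised beam takes the average of the TE and TM values.
#'
#' @inheritParams harrick_penetration_depth
#' @param polarization `"unpolarised"`, `"TE"` or `"TM"`, or a TE power
#'   fraction in \[0, 1\].
#' @return Effective thickness in um (per reflection).
#' @export
harrick_effective_thickness <- function(lambda_um, angle_deg, n1, n2,
                                        polarization = "unpolarised") {
  th <- angle_deg * pi / 180
  n21 <- n2 / n1
  s2 <- sin(th)^2
  disc <- s2 - n21^2
  if (any(disc <= 0))
    stop_computation("angle at or below the critical angle: ",
                     "no evanescent field")
  lam1 <- lambda_um / n1
  common <- n21 * lam1 * cos(th) / (pi * (1 - n21^2) * sqrt(disc))
  de_te <- common
  de_tm <- common * (2 * s2 - n21^2) / ((1 + n21^2) * s2 - n21^2)
  frac <- if (is.character(polarization)) {
    switch(match.arg(polarization, c("unpolarised", "TE", "TM")),
           unpolarised = 0.5, TE = 1, TM = 0)
  } else {
    if (polarization < 0 || polarization > 1)
      stop_argument("TE fraction must lie in [0, 1]")
    polarization
  }
  frac * de_te + (1 - frac) * de_tm
}

# Angular quadrature nodes and normalised weights for an atr_config.
# Deterministic 21-node Gauss-Legendre over the declared spread.
angle_quadrature <- function(config, n_nodes = 21L) {
  th0 <- config$angle_deg
  switch(config$angle_spread,
         delta = list(angles = th0, weights = 1),
         uniform = {
           gl <- pracma::gaussLegendre(n_nodes, th0 - config$spread_deg,
                                       th0 + config$spread_deg)
           list(angles = gl$x, weights = gl$w / sum(gl$w))
         },
         gaussian = {
           gl <- pracma::gaussLegendre(n_nodes, th0 - 3 * config$spread_deg,
                                       th0 + 3 * config$spread_deg)
           w <- gl$w * stats::dnorm(gl$x, th0, config$spread_deg)
           list(angles = gl$x, weights = w / sum(w))
         })
}

#' Forward ATR absorbance simulation
#'
#' For each wavelength, the per-reflection effective thickness is averaged
#' over the configured angular distribution (fixed-node Gauss-Legendre
#' quadrature) and polarisation mix, then
#'
#'   a(lambda) = N <d_e> 4 pi k(lambda) log10 e / lambda
#'
#' -- the weak-absorption Beer-Lambert forward model with d = N d_ep.
#' The sample's own real index enters the effective thickness, so the
#' simulator reproduces the index-contrast fluctuations that the empirical
#' calibration must absorb.  Optional Gaussian absorbance noise is
#' seeded explicitly; the default is noiseless.
#'
#' @param index a [complex_index_spectrum()] of the sample.
#' @param config an [atr_config()].
#' @param noise_sd standard deviation of additive absorbance noise.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return An [absorbance_spectrum()] referenced to atmosphere.
#' @export
simulate_atr_absorbance <- function(index, config = atr_config(),
                                    noise_sd = 0, seed = NULL) {
  stopifnot(inherits(index, "complex_index_spectrum"),
            inherits(config, "atr_config"))
  wl <- axis_wavelength(index$axis)
  quad <- angle_quadrature(config)
  n1 <- config$crystal_index
  crit <- asin(pmin(max(index$n) / n1, 1)) * 180 / pi
  if (any(quad$angles <= crit))
    stop_computation(sprintf(
      "angle distribution reaches %.3g deg, at or below the critical angle %.3g deg",
      min(quad$angles), crit))
  de <- numeric(length(wl))
  for (q in seq_along(quad$angles)) {
    de <- de + quad$weights[q] *
      harrick_effective_thickness(wl, quad$angles[q], n1, index$n,
                                  polarization = config$te_fraction)
  }
  a <- config$n_reflections * de * 4 * pi * index$k * LOG10E / wl
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a <- a + stats::rnorm(length(a), sd = noise_sd)
  }
  absorbance_spectrum(index$axis, a, reference = "atmosphere",
                      n_reflections = config$n_reflections)
}

#' Pseudo-water ground truth: model plus matching standard table
#'
#' A three-oscillator Lorentz fixture emulating the dominant absorptions of
#' liquid water -- the O-H stretch near 3 um, the H-O-H bend near 6.1 um
#' and the broad libration band beyond 10 um -- with eps_inf set so that
#' n(2 um) is close to 1.3.  Returns both the model and its exact (n, k)
#' tabulated as a [water_standard()], so every stage can calibrate against
#' self-consistent "literature" values without downloading data.  The
#' tabulation covers 1.67--200 um (wavenumbers down to 50 cm^-1).
#'
#' @param axis optional [spectral_axis()] for the tabulation; must span at
#'   least 1.67--200 um.  Default: 50--6000 cm^-1 at `step_cm1`.
#' @param step_cm1 grid step of the default tabulation (cm^-1).
#' @return A list with elements `model` ([lorentz_model()]) and `standard`
#'   ([water_standard()]).
#' @export
make_pseudo_water <- function(axis = NULL, step_cm1 = 2) {
  model <- lorentz_model(
    eps_inf = 1.765,
    centers   = c(3350,  1640,  600),   # O-H stretch, H-O-H bend, libration
    strengths = c(9.0e5, 6.5e4, 1.8e5),
    gammas    = c(350,   120,   300))
  if (is.null(axis))
    axis <- spectral_axis(seq(50, 6000, by = step_cm1), "wavenumber")
  wl <- axis_wavelength(axis)
  if (min(wl) > 1.67 || max(wl) < 200)
    stop_argument("pseudo-water axis must span at least 1.67-200 um")
  ci <- model_complex_index(model, axis)
  list(model = model,
       standard = water_standard(axis, ci$n, ci$k))
}

#' Dilute-solute synthetic model: pseudo-water plus one weak band
#'
#' Adds a single weak oscillator to a pseudo-water model, emulating a
#' dilute analyte in aqueous solution.  The defaults put the band at
#' 2250 cm^-1 (4.4 um), inside a low-loss window of water, with a strength
#' giving a peak index increment delta-k of about 0.002 -- the regime the
#' differential pathway is designed for, where water still controls the
#' penetration depth and the analyte perturbs it only to first order.
#'
#' @param model a pseudo-water [lorentz_model()].
#' @param center band centre (cm^-1).
#' @param strength oscillator strength (cm^-2).
#' @param gamma damping (cm^-1).
#' @return The augmented [lorentz_model()].
#' @export
make_dilute_solution <- function(model, center = 2250, strength = 486,
                                 gamma = 40) {
  add_oscillators(model, center, strength, gamma)
}

#' Blood-like synthetic model: pseudo-water plus amide bands
#'
#' Adds two oscillators at the amide I (6.05 um) and amide II (6.49 um)
#' protein backbone positions to a pseudo-water model, giving a synthetic
#' stand-in with the qualitative spectral signature that distinguishes
#' whole blood from water in the mid-infrared.
#'
#' @param model a pseudo-water [lorentz_model()].
#' @param strength_scale multiplies the default amide strengths.
#' @return The augmented [lorentz_model()].
#' @export
make_blood_like <- function(model, strength_scale = 1) {
  add_oscillators(model,
                  centers   = c(1e4 / 6.05, 1e4 / 6.49),
                  strengths = strength_scale * c(2.6e3, 3.4e3),
                  gammas    = c(45, 55))
}
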