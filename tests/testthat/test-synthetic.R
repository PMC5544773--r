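test_that("an oscillator-free model reduces to sqrt(eps_inf)", {
  ax <- measured_axis(step = 40)
  ci <- model_complex_index(lorentz_model(1.777), ax)
  expect_equal(ci$n, rep(sqrt(1.777), axis_length(ax)), tolerance = 1e-12)
  expect_equal(ci$k, rep(0, axis_length(ax)))
})

test_that("a single oscillator peaks at its centre and forms a KK pair", {
  ax <- spectral_axis(seq(500, 3500, by = 2), "wavenumber")
  m <- lorentz_model(1.7, 2000, 1e4, 20)
  ci <- model_complex_index(m, ax)
  nu <- axis_wavenumber(ax)
  expect_lt(abs(nu[which.max(ci$k)] - 2000), 2 + 1e-9)
  s <- model_susceptibility(m, nu)
  chi1 <- kk_real_from_imag(nu, s$chi2)
  expect_lt(max(abs(chi1 - s$chi1)) / diff(range(s$chi1)), 0.01)
})

test_that("invalid Lorentz parameters are refused", {
  expect_error(lorentz_model(0.5), class = "atr_argument_error")
  expect_error(lorentz_model(1.7, 2000, -1, 60), class = "atr_argument_error")
  expect_error(lorentz_model(1.7, 2000, 1e5, 0), class = "atr_argument_error")
  expect_error(lorentz_model(1.7, 2000, 1e5, c(60, 70)),
               class = "atr_argument_error")
})

test_that("penetration depth matches the hand-evaluated 45 degree ZnSe/water case", {
  # d_p = lambda / (2 pi n1 sqrt(sin^2 45 - (1.33/2.4)^2)) = lambda / 6.623
  dp <- harrick_penetration_depth(5, 45, 2.4, 1.33)
  expect_equal(dp, 5 / 6.623, tolerance = 1e-4)
  expect_equal(dp / 5, 0.1510, tolerance = 1e-3)
  # deeper penetration as the index contrast drops
  n2 <- seq(0.2, 1.6, by = 0.2)
  dps <- vapply(n2, function(x) harrick_penetration_depth(5, 45, 2.4, x), 0)
  expect_true(all(diff(dps) > 0))
  # at (or below) the critical angle there is no evanescent field
  crit <- asin(1.33 / 2.4) * 180 / pi
  expect_error(harrick_penetration_depth(5, crit, 2.4, 1.33),
               class = "atr_computation_error")
})

test_that("unpolarised effective thickness is the TE/TM average", {
  te <- harrick_effective_thickness(5, 45, 2.4, 1.33, "TE")
  tm <- harrick_effective_thickness(5, 45, 2.4, 1.33, "TM")
  un <- harrick_effective_thickness(5, 45, 2.4, 1.33, "unpolarised")
  expect_equal(un, (te + tm) / 2, tolerance = 1e-12)
  expect_equal(harrick_effective_thickness(5, 45, 2.4, 1.33, 0.25),
               0.25 * te + 0.75 * tm, tolerance = 1e-12)
  expect_gt(tm, te)  # TM couples more strongly above the critical angle
})

test_that("simulated absorbance is zero for lossless samples and linear in N", {
  ax <- measured_axis(step = 40)
  lossless <- model_complex_index(lorentz_model(1.777), ax)
  a0 <- simulate_atr_absorbance(lossless, atr_config())
  expect_equal(a0$a, rep(0, axis_length(ax)))
  wci <- water_index_on(ax)
  a10 <- simulate_atr_absorbance(wci, atr_config(n_reflections = 10))
  a20 <- simulate_atr_absorbance(wci, atr_config(n_reflections = 20))
  expect_equal(a20$a, 2 * a10$a, tolerance = 1e-12)
  # angle distributions reaching the critical angle are refused
  expect_error(
    simulate_atr_absorbance(wci, atr_config(angle_deg = 40,
                                            angle_spread = "uniform",
                                            spread_deg = 3)),
    class = "atr_computation_error")
})

test_that("noise injection is seeded and reproducible", {
  ax <- measured_axis(step = 40)
  wci <- water_index_on(ax)
  a1 <- simulate_atr_absorbance(wci, noise_sd = 1e-3, seed = 5)
  a2 <- simulate_atr_absorbance(wci, noise_sd = 1e-3, seed = 5)
  a3 <- simulate_atr_absorbance(wci, noise_sd = 1e-3, seed = 6)
  expect_identical(a1$a, a2$a)
  expect_false(identical(a1$a, a3$a))
})

test_that("pseudo-water has the water-like band structure and a causal (n, k) pair", {
  std <- pw_fix$standard
  wl_dense <- seq(2, 12, by = 0.005)
  k <- standard_k(std, wl_dense)
  # local maxima near the O-H stretch (3 um) and H-O-H bend (6.1 um)
  stretch <- wl_dense[wl_dense > 2.5 & wl_dense < 3.5]
  expect_lt(abs(stretch[which.max(standard_k(std, stretch))] - 3), 0.15)
  bend <- wl_dense[wl_dense > 5.5 & wl_dense < 7]
  expect_lt(abs(bend[which.max(standard_k(std, bend))] - 6.1), 0.15)
  # n near 1.3 at the 2 um anchor
  expect_lt(abs(standard_n(std, 2) - 1.3), 0.05)
  # (n, k) from the model are a numerical KK pair over the tabulated band
  nu <- std$nu
  n_kk <- kk_real_from_imag(nu, std$k_ref)
  i0 <- which.min(abs(nu - 5000))
  n_kk <- n_kk - n_kk[i0] + std$n_ref[i0]
  in_band <- nu > 500 & nu < 5500
  expect_lt(max(abs(n_kk[in_band] - std$n_ref[in_band])) /
              diff(range(std$n_ref)), 0.01)
  # a too-narrow axis is refused
  expect_error(make_pseudo_water(spectral_axis(seq(600, 6000, 4),
                                               "wavenumber")),
               class = "atr_argument_error")
})

test_that("forward/inverse closure holds for delta and spread-angle beams", {
  ax <- measured_axis(step = 8)
  wci <- water_index_on(ax)
  k_ref <- standard_k(pw_fix$standard, axis_wavelength(ax))
  for (cfg in list(atr_config(),
                   atr_config(angle_spread = "gaussian", spread_deg = 2))) {
    wabs <- simulate_atr_absorbance(wci, cfg)
    deff <- calibrate_deff(wabs, pw_fix$standard)
    k_est <- k_from_absorbance(wabs, deff)
    v <- deff$valid
    expect_lt(max(abs(k_est$k[v] - k_ref[v]) / k_ref[v]), 0.005)
  }
})
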