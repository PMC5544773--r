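test_that("the transform maps zero to zero, is linear, and rejects uneven grids", {
  nu <- seq(100, 4000, by = 10)
  expect_equal(kk_real_from_imag(nu, rep(0, length(nu))),
               rep(0, length(nu)))
  set.seed(3)
  chi2 <- abs(stats::rnorm(length(nu)))
  c1 <- kk_real_from_imag(nu, chi2)
  c3 <- kk_real_from_imag(nu, 3.7 * chi2)
  expect_lt(max(abs(c3 - 3.7 * c1)), 1e-12 * max(abs(c1)))
  expect_error(kk_real_from_imag(c(nu[-1], 4011), chi2),
               class = "atr_argument_error")
})

test_that("Maclaurin transform recovers the closed-form Lorentz real part", {
  set.seed(42)
  for (rep in 1:4) {
    n_osc <- sample(1:3, 1)
    centers <- runif(n_osc, 1500, 3000)
    gammas <- runif(n_osc, 60, 250)
    strengths <- runif(n_osc, 1e4, 5e5)
    m <- lorentz_model(1.5, centers, strengths, gammas)
    # span >= 50 linewidths each side at >= 10 points per linewidth
    gmin <- min(gammas)
    lo <- max(gmin / 10, min(centers) - 50 * max(gammas))
    hi <- max(centers) + 50 * max(gammas)
    h <- gmin / 12
    nu <- seq(lo, hi, by = h)
    ref <- model_susceptibility(m, nu)
    chi1 <- kk_real_from_imag(nu, ref$chi2)
    err <- max(abs(chi1 - ref$chi1)) / diff(range(ref$chi1))
    expect_lt(err, 0.01)
  }
})

test_that("extension splices the standard seamlessly and obeys the zero high policy", {
  std <- pw_fix$standard
  ax <- measured_axis(step = 4)
  wl <- axis_wavelength(ax)
  k_meas <- k_spectrum(ax, standard_k(std, wl))
  ext <- extend_with_standard(k_meas, std)
  h <- diff(ext$frequency[1:2])
  expect_gt(h, 0)
  expect_lt(max(abs(diff(ext$frequency) - h)), 1e-6 * h)
  # measured k identical to the standard -> junction exactly seamless
  in_cov <- ext$frequency >= min(std$nu) & ext$frequency <= max(std$nu)
  expect_lt(max(abs(ext$chi2[in_cov] -
                    standard_k(std, 1e4 / ext$frequency[in_cov]))), 1e-9)
  # grid reaches the far-infrared limit and twice the measured maximum
  expect_lt(ext$frequency[1], 60)       # ~200 um
  expect_gt(max(ext$frequency), 1.99 * 6000 - 10)
  expect_true(all(ext$chi2[ext$frequency > 6001] == 0))
  # "none" policy: nothing above the measured band
  ext2 <- extend_with_standard(k_meas, std,
                               extension_config(high_extension = "none"))
  expect_lt(max(ext2$frequency), 6000 + 1e-9)
})

test_that("a junction mismatch is cross-faded without a step larger than the mismatch", {
  std <- pw_fix$standard
  ax <- measured_axis(step = 4)
  wl <- axis_wavelength(ax)
  delta <- 0.05
  k_meas <- k_spectrum(ax, standard_k(std, wl) + delta)
  ext <- extend_with_standard(k_meas, std)
  # the steps attributable to the mismatch (relative to a seamless splice)
  # stay far below delta: the fade spreads it over the junction window
  ext0 <- extend_with_standard(k_spectrum(ax, standard_k(std, wl)), std)
  low_side <- which(ext$frequency < 1000)  # splice + junction region
  expect_lt(max(abs(diff(ext$chi2[low_side]) - diff(ext0$chi2[low_side]))),
            delta / 5)
  # below the splice the standard's own k is used
  low <- ext$frequency < 1e4 / 15 - 8
  expect_lt(max(abs(ext$chi2[low] -
                    standard_k(std, 1e4 / ext$frequency[low]))), 1e-9)
  # well above the junction the measurement (with its offset) is kept
  hi_band <- ext$frequency > 1000 & ext$frequency < 3000
  expect_lt(max(abs(ext$chi2[hi_band] -
                    (standard_k(std, 1e4 / ext$frequency[hi_band]) + delta))),
            1e-6)
})

test_that("offset anchoring pins n to the standard at the anchor and preserves differences", {
  std <- pw_fix$standard
  ax <- measured_axis(step = 4)
  wl <- axis_wavelength(ax)
  n_true <- standard_n(std, wl)
  k_true <- standard_k(std, wl)
  ci_shift <- complex_index_spectrum(ax, n_true - 0.3, k_true)
  out <- offset_to_anchor(ci_shift, std)
  expect_lt(max(abs(out$n - n_true)), 1e-9)
  # already anchored -> unchanged
  out2 <- offset_to_anchor(out, std)
  expect_lt(max(abs(out2$n - out$n)), 1e-12)
  # pairwise differences are invariant under the shift
  expect_equal(diff(out$n), diff(ci_shift$n), tolerance = 1e-12)
  # anchor outside the band is refused
  bad <- extension_config(anchor_um = 30)
  expect_error(offset_to_anchor(ci_shift, std, bad),
               class = "atr_argument_error")
})

test_that("the full chain on the water standard reproduces its own n (self-consistency)", {
  sc <- water_selfcheck(pw_fix$standard)
  expect_lt(sc$max_abs_error, 0.01)
})

test_that("without extrapolation the transform diverges at long wavelengths", {
  sc <- water_selfcheck(pw_fix$standard)
  expect_gte(sc$divergence_ratio, 10)
  # the unextended deviation at the band edge is substantial in absolute terms
  expect_gt(sc$dev_long, 0.05)
})

test_that("the k -> n map is affine: water plus a weak band maps to the sum of responses", {
  std <- pw_fix$standard
  ax <- measured_axis(step = 4)
  wl <- axis_wavelength(ax)
  k_w <- standard_k(std, wl)
  osc <- lorentz_model(1, 2250, 486, 40)
  s <- model_susceptibility(osc, axis_wavenumber(ax))
  n0 <- standard_n(std, 1e4 / 2250)  # local background index at the band
  dk <- s$chi2 / (2 * n0)
  dn_true <- s$chi1 / (2 * n0)
  n_w <- kk_n_from_k(k_spectrum(ax, k_w), std)$n
  n_sum <- kk_n_from_k(k_spectrum(ax, k_w + dk), std)$n
  dn_est <- n_sum - n_w
  # the offset is re-anchored per run; compare shapes after matching at 2 um
  i2 <- which.min(abs(wl - 2))
  dn_est <- dn_est - dn_est[i2] + dn_true[i2]
  expect_lt(max(abs(dn_est - dn_true)) / diff(range(dn_true)), 0.01)
})
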