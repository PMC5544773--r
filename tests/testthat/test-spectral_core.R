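test_that("wavenumber/wavelength conversion matches the instrument band and is an involution", {
  ax <- spectral_axis(c(6000, 600), "wavenumber")
  wl <- convert_axis(ax, "wavelength")
  expect_equal(signif(wl$values, 3), c(1.67, 16.7))
  expect_equal(wl$unit, "wavelength")
  # monotonicity sense reverses: descending wavenumber -> ascending wavelength
  expect_true(all(diff(wl$values) > 0))

  set.seed(11)
  for (i in 1:20) {
    v <- sort(runif(50, 10, 9000))
    if (i %% 2 == 0) v <- rev(v)
    ax <- spectral_axis(v, if (i %% 3 == 0) "wavelength" else "wavenumber")
    back <- convert_axis(convert_axis(
      ax, setdiff(c("wavenumber", "wavelength"), ax$unit)), ax$unit)
    expect_lt(max(abs(back$values - ax$values) / abs(ax$values)), 1e-12)
  }
})

test_that("invalid axes are refused", {
  expect_error(spectral_axis(5, "wavenumber"), class = "atr_argument_error")
  expect_error(spectral_axis(c(1, 1, 2)), class = "atr_argument_error")
  expect_error(spectral_axis(c(-1, 5)), class = "atr_argument_error")
  expect_error(spectral_axis(c(0, 5)), class = "atr_argument_error")
  expect_error(spectral_axis(c(1, NA)), class = "atr_argument_error")
})

test_that("resampling to even frequency preserves even grids, lines, and smooth functions", {
  nu <- seq(600, 6000, by = 4)
  s <- absorbance_spectrum(spectral_axis(nu, "wavenumber"), 0.1 + nu * 1e-5)
  # identity on an already-even grid
  r <- resample_even_frequency(s, length(nu))
  expect_lt(max(abs(r$a - s$a)), 1e-12)
  expect_identical(r$reference, s$reference)
  expect_identical(r$n_reflections, s$n_reflections)
  # linear data reproduced exactly on any new even grid
  r2 <- resample_even_frequency(s, 731)
  nu2 <- axis_wavenumber(r2$axis)
  expect_lt(max(abs(r2$a - (0.1 + nu2 * 1e-5))), 1e-10)
  # smooth oscillatory data: compare against the analytic values.  The
  # monotone-safe interpolant limits slopes at local extrema, so accuracy
  # there is O(h^2); direct evaluation on this grid gives 1.96e-4.
  s3 <- absorbance_spectrum(spectral_axis(nu, "wavenumber"),
                            1 + sin(nu / 100))
  r3 <- resample_even_frequency(s3, 2 * length(nu) - 1)
  nu3 <- axis_wavenumber(r3$axis)
  expect_lt(max(abs(r3$a - (1 + sin(nu3 / 100)))), 5e-4)
  expect_error(resample_even_frequency(s, 1), class = "atr_argument_error")
})

test_that("spectrum file round trip preserves values and metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  nu <- seq(600, 6000, length.out = 1351)
  set.seed(7)
  s <- absorbance_spectrum(spectral_axis(nu, "wavenumber"),
                           runif(1351, 0, 2), reference = "water",
                           n_reflections = 10)
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_identical(r$reference, "water")
  expect_identical(r$n_reflections, 10L)
  expect_identical(r$axis$unit, "wavenumber")
  expect_lt(max(abs(r$axis$values - nu) / nu), 1e-9)
  expect_lt(max(abs(r$a - s$a) / pmax(abs(s$a), 1e-12)), 1e-9)
})

test_that("spectrum parser reports malformed input with its line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# unit=cm-1 reference=atmosphere n_reflections=3",
               "3000,0.5", "3004,NaN", "3008,0.7"), path)
  expect_error(read_spectrum(path), "line 3", class = "atr_argument_error")
  writeLines(c("3000,0.5", "3004,0.6"), path)
  expect_error(read_spectrum(path), class = "atr_argument_error")
  writeLines(c("# reference=atmosphere", "3000,0.5", "3004,0.6"), path)
  expect_error(read_spectrum(path), "unit", class = "atr_argument_error")
  # minimal two-column file with an optional title row
  writeLines(c("# unit=cm-1 reference=atmosphere n_reflections=10",
               "wavenumber,absorbance", "3000,0.5", "3004,0.6"), path)
  s <- read_spectrum(path)
  expect_equal(s$a, c(0.5, 0.6))
})

test_that("the JCAMP-DX reader handles a linear-abscissa absorbance block", {
  path <- withr::local_tempfile(fileext = ".jdx")
  nu <- seq(600, 680, by = 4)
  a <- round(0.2 + 0.01 * sin(nu / 10), 6)
  rows <- vapply(split(seq_along(nu), ceiling(seq_along(nu) / 5)),
                 function(ix) paste(c(format(nu[ix[1]]), format(a[ix])),
                                    collapse = " "), "")
  writeLines(c("##TITLE=synthetic check", "##XUNITS=1/CM",
               "##YUNITS=ABSORBANCE", "##FIRSTX=600", "##LASTX=680",
               sprintf("##NPOINTS=%d", length(nu)), "##XFACTOR=1",
               "##YFACTOR=1", "##$REFERENCE=water", "##$NREFLECTIONS=10",
               "##XYDATA=(X++(Y..Y))", rows, "##END="), path)
  s <- read_spectrum(path, dialect = "jcamp")
  expect_equal(axis_wavenumber(s$axis), nu)
  expect_equal(s$a, a, tolerance = 1e-9)
  expect_identical(s$reference, "water")
  expect_identical(s$n_reflections, 10L)
})

test_that("water standard interpolation refuses queries outside coverage", {
  std <- pw_fix$standard
  expect_error(standard_k(std, 250), class = "atr_argument_error")
  expect_error(standard_n(std, 1.0), class = "atr_argument_error")
  # inside coverage: interpolation reproduces tabulated nodes
  wl <- 1e4 / std$nu[c(10, 500, 1500)]
  expect_equal(standard_k(std, wl), std$k_ref[c(10, 500, 1500)],
               tolerance = 1e-12)
})
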