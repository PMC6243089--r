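# Gaussian band decomposition, model selection, dipole ratios, populations.

gauss_y <- function(x, c0, fw, h) h * exp(-4 * log(2) * (x - c0)^2 / fw^2)

test_that("second-derivative detection locates resolvable bands", {
  x <- seq(1900, 1970, by = 0.25)
  s1 <- linear_spectrum(x, gauss_y(x, 1939.4, 9, 1))
  cand <- second_derivative_bands(s1)
  expect_length(cand, 1)
  expect_lt(abs(cand - 1939.4), 0.26)
  s2 <- linear_spectrum(x, gauss_y(x, 1928, 7, 1) + gauss_y(x, 1943, 7, 0.7))
  cand2 <- second_derivative_bands(s2)
  expect_length(cand2, 2)
  expect_lt(abs(cand2[1] - 1928), 1)
  expect_lt(abs(cand2[2] - 1943), 1)
})

test_that("detection of a resolvable doublet survives 1% noise", {
  x <- seq(1900, 1970, by = 0.25)
  y0 <- gauss_y(x, 1928, 7, 1) + gauss_y(x, 1943, 7, 0.7)
  hits <- 0
  set.seed(303)
  for (i in 1:50) {
    y <- y0 + rnorm(length(x), sd = 0.01)
    cand <- second_derivative_bands(linear_spectrum(x, y))
    near <- sum(vapply(c(1928, 1943), function(c0) any(abs(cand - c0) < 1.5), TRUE))
    if (near == 2) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("the strong-dipole shoulder is detectable on the 2D projection", {
  # on the linear composite the high band produces no separate curvature
  # minimum; the dipole^4-weighted projection resolves both components
  lin_cand <- second_derivative_bands(fx_linear("pdx"))
  expect_true(any(abs(lin_cand - 1931.3) < 1))
  p0 <- diagonal_projection(fx_series("pdx")$spectra[[1]])
  proj_cand <- second_derivative_bands(p0)
  expect_length(proj_cand, 2)
  expect_lt(abs(proj_cand[1] - 1931.3), 1)
  expect_lt(abs(proj_cand[2] - 1936.8), 1)
})

test_that("an exact two-Gaussian spectrum is recovered to four significant figures", {
  x <- seq(1900, 1970, by = 0.25)
  y <- gauss_y(x, 1929.5, 8, 1) + gauss_y(x, 1944.2, 6, 0.6) + 0.01
  f <- fit_gaussians(linear_spectrum(x, y), 2, init = c(1930, 1944))
  cmp <- f$components
  expect_equal(cmp$center, c(1929.5, 1944.2), tolerance = 1e-4)
  expect_equal(cmp$fwhm, c(8, 6), tolerance = 5e-4)
  expect_equal(cmp$height, c(1, 0.6), tolerance = 5e-4)
  expect_equal(f$baseline, 0.01, tolerance = 1e-3)
})

test_that("single-Gaussian fit of the wt band reproduces the published values", {
  f <- fit_gaussians(fx_linear("wt"), 1)
  expect_equal(f$components$center, 1939.4, tolerance = 0.1 / 1939.4)
  expect_equal(f$components$fwhm, 12.9, tolerance = 0.2 / 12.9)
})

test_that("two-Gaussian decomposition of the Pdx composite recovers the area split", {
  p0 <- diagonal_projection(fx_series("pdx")$spectra[[1]])
  cand <- second_derivative_bands(p0)
  f <- fit_gaussians(fx_linear("pdx"), 2, init = cand)
  # printed uncertainty on the relative areas is +-5 area percent
  expect_equal(f$components$area_frac[1], 0.65, tolerance = 0.05 / 0.65)
  expect_equal(f$components$area_frac[2], 0.35, tolerance = 0.05 / 0.35)
})

test_that("F-test model selection distinguishes one- from two-state samples", {
  expect_identical(as.integer(select_model(fx_linear("wt"))), 1L)
  p0 <- diagonal_projection(fx_series("pdx")$spectra[[1]])
  cand_p <- second_derivative_bands(p0)
  expect_identical(as.integer(select_model(fx_linear("pdx"),
                                           init = list(n2 = cand_p))), 2L)
  expect_identical(as.integer(select_model(fx_linear("l358p"))), 2L)
})

test_that("diagonal slice matches nearest-grid extraction and shows the shoulder", {
  s <- fx_series("wt")$spectra[[1]]
  sl <- diagonal_slice(s)
  expect_lt(abs(sl$wavenumber[which.max(sl$absorbance)] - 1939.4), 1.2)
  # nearest-neighbour oracle on the native grid
  nn <- vapply(seq_along(s$omega1), function(i) s$amplitude[i, i], 0)
  on_grid <- approx(sl$wavenumber, sl$absorbance, xout = s$omega1)$y
  ok <- !is.na(on_grid)
  expect_equal(on_grid[ok], nn[ok], tolerance = 0.02)
  # Pdx: high-frequency shoulder more pronounced in the slice than linear
  slp <- diagonal_slice(fx_series("pdx")$spectra[[1]])
  lin <- fx_linear("pdx")
  ratio_of <- function(x, y) {
    hi <- max(y[x >= 1935 & x <= 1941]); lo <- max(y[x >= 1928 & x <= 1934])
    hi / lo
  }
  expect_gt(ratio_of(slp$wavenumber, slp$absorbance),
            ratio_of(lin$wavenumber, lin$absorbance))
})

test_that("first moment of a symmetric single band is waiting-time independent", {
  ser <- fx_series("wt")
  m1 <- vapply(ser$spectra, function(s)
    first_moment(diagonal_slice(s), window = c(1925, 1954)), 0)
  expect_lt(max(m1) - min(m1), 0.05)
})

test_that("dipole ratio from matched fits behaves as a ratio of ratios", {
  x <- seq(1900, 1970, by = 0.25)
  y <- gauss_y(x, 1931, 8, 1) + gauss_y(x, 1943, 8, 0.5)
  fa <- fit_gaussians(linear_spectrum(x, y), 2, init = c(1931, 1943))
  expect_equal(dipole_ratio(fa, fa), 1, tolerance = 1e-9)
  # unpaired components rejected
  y2 <- gauss_y(x, 1920, 8, 1) + gauss_y(x, 1955, 8, 0.5)
  fb <- fit_gaussians(linear_spectrum(x, y2), 2, init = c(1920, 1955))
  expect_error(dipole_ratio(fa, fb), "paired")
})

test_that("full Pdx pipeline recovers the injected transition-dipole ratio", {
  an <- fx_analysis("pdx")
  expect_equal(an$dipole_ratio, 1.27, tolerance = 0.03 / 1.27)
  expect_equal(round(an$dipole_ratio, 1), 1.3)
})

test_that("dipole-corrected populations reproduce the published arithmetic", {
  expect_equal(populations(c(0.5, 0.5), 1)$populations, c(0.5, 0.5))
  p <- populations(c(0.65, 0.35), 1.27)
  expect_equal(p$populations, c(0.75, 0.25), tolerance = 0.01 / 0.25)
  p2 <- populations(c(0.30, 0.70), 1.27)
  expect_equal(p2$populations, c(0.409, 0.591), tolerance = 0.002)
  expect_equal(populations(c(0, 1), 1.5)$populations, c(0, 1))
})

test_that("populations invert the simulator's intensity rules for any dipole ratio", {
  for (r in c(1, 1.27, 1.6, 2)) {
    for (p_low in c(0.2, 0.5, 0.75)) {
      areas <- c(p_low * 1, (1 - p_low) * r^2)
      areas <- areas / sum(areas)
      est <- populations(areas, r)$populations
      expect_equal(est, c(p_low, 1 - p_low), tolerance = 1e-9)
    }
  }
})

test_that("frozen-basis amplitude refits preserve shapes and quantify areas", {
  x <- seq(1900, 1970, by = 0.25)
  y <- gauss_y(x, 1931, 8, 1) + gauss_y(x, 1943, 8, 0.5)
  f <- fit_gaussians(linear_spectrum(x, y), 2, init = c(1931, 1943))
  y2 <- gauss_y(x, 1931, 8, 0.4) + gauss_y(x, 1943, 8, 0.9) + 0.02
  f2 <- fit_band_amplitudes(linear_spectrum(x, y2), f)
  expect_equal(f2$components$height, c(0.4, 0.9), tolerance = 0.01)
  expect_equal(f2$components$fwhm, f$components$fwhm)
})
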