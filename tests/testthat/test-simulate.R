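# Forward simulator: response-function 2D spectra, series, pump-probe traces.

test_that("fixed seeds give bit-identical series; seeds change only the noise", {
  m <- p450_fixture("wt", noise_sd = 0.02)
  s1 <- simulate_tw_series(m, t_w_list = c(0.25, 5, 15, 30), seed = 11)
  s2 <- simulate_tw_series(m, t_w_list = c(0.25, 5, 15, 30), seed = 11)
  expect_identical(s1$spectra[[2]]$amplitude, s2$spectra[[2]]$amplitude)
  s3 <- simulate_tw_series(m, t_w_list = c(0.25, 5, 15, 30), seed = 12)
  expect_false(identical(s1$spectra[[2]]$amplitude, s3$spectra[[2]]$amplitude))
  # noiseless part identical: differences are pure noise with sd ~ sqrt(2)*sd
  m0 <- p450_fixture("wt", noise_sd = 0)
  s0 <- simulate_tw_series(m0, t_w_list = c(0.25, 5, 15, 30))
  d1 <- s1$spectra[[1]]$amplitude - s0$spectra[[1]]$amplitude
  d3 <- s3$spectra[[1]]$amplitude - s0$spectra[[1]]$amplitude
  ref <- max(s0$spectra[[1]]$amplitude)
  expect_equal(sd(d1) / ref, 0.02, tolerance = 0.05)
  expect_lt(abs(mean(d1)), 0.002 * ref)
  expect_equal(sd(d1 - d3) / ref, 0.02 * sqrt(2), tolerance = 0.07)
})

test_that("short-waiting-time 2D band is highly elongated along the diagonal", {
  s <- fx_series("wt")$spectra[[1]]
  dd <- seq(-15, 15, by = 0.1)
  diag_w <- fwhm_of(dd, ir2d:::.interp2(s, 1939.4 + dd, 1939.4 + dd))
  anti_w <- fwhm_of(dd, ir2d:::.interp2(s, 1939.4 + dd, 1939.4 - dd))
  expect_gt(diag_w / anti_w, 2)
})

test_that("complete spectral diffusion collapses the diagonal elongation", {
  p <- ffcf_params(1.6, 3.0, 20.7, 0, t1_lifetime = Inf)
  m <- mixture_model(list(spectral_component(1939.4, p)), noise_sd = 0)
  s <- simulate_2d(m, 150)
  dd <- seq(-10, 10, by = 0.1)
  diag_w <- fwhm_of(dd, ir2d:::.interp2(s, 1939.4 + dd, 1939.4 + dd))
  anti_w <- fwhm_of(dd, ir2d:::.interp2(s, 1939.4 + dd, 1939.4 - dd))
  expect_equal(diag_w / anti_w, 1, tolerance = 0.05)
})

test_that("diagonal-slice first moment of the mixture shifts blue with waiting time", {
  m <- fx_model("pdx")
  tws <- c(0.25, 20, 32, 44)
  m1 <- vapply(tws, function(tw)
    first_moment(diagonal_slice(simulate_2d(m, tw)), window = c(1920, 1950)),
    0)
  expect_true(all(diff(m1) > 0))
})

test_that("2D amplitude scales as dipole^4, linear area as dipole^2", {
  amps <- vapply(c(0.9, 1.27, 1.5), function(dip) {
    cm <- spectral_component(1935, wt_ffcf_ref(), dipole = dip)
    m <- mixture_model(list(cm), noise_sd = 0)
    max(simulate_2d(m, 1)$amplitude)
  }, 0)
  expect_equal(amps / amps[1], (c(0.9, 1.27, 1.5) / 0.9)^4, tolerance = 1e-6)
  areas <- vapply(c(0.9, 1.27, 1.5), function(dip) {
    cm <- spectral_component(1935, wt_ffcf_ref(), dipole = dip)
    s <- synth_linear(cm, seq(1880, 1990, by = 0.1))
    sum(s$absorbance) * 0.1
  }, 0)
  expect_equal(areas / areas[1], (c(0.9, 1.27, 1.5) / 0.9)^2, tolerance = 1e-6)
})

test_that("noiseless single-component spectra are symmetric in the fundamental region", {
  # region tight enough to exclude the anharmonically shifted 1-2 ridge
  s <- fx_series("wt")$spectra[[3]]
  k <- which(s$omega1 >= 1930 & s$omega1 <= 1949)
  A <- s$amplitude[k, k]
  expect_lt(max(abs(A - t(A))) / max(A), 0.02)
})

test_that("noiseless wt CLS decay matches the normalized inhomogeneous FFCF", {
  ser <- fx_series("wt")
  win <- c(1939.4 - 0.6 * 12.9, 1939.4 + 0.6 * 12.9)
  cls <- vapply(ser$spectra, function(s)
    unname(cls_of(extract_center_line(s, win))["slope"]), 0)
  cn <- (9 * exp(-ser$t_w / 20.7) + 4.1^2) / (9 + 4.1^2)
  pred <- cls[1] * cn / cn[1]
  expect_lt(max(abs(cls - pred)), 0.02)
})

test_that("degenerate mixtures decay as a single exponential", {
  f <- ffcf_params(1.6, 3.0, 20.7, 4.1, t1_lifetime = 15)
  m <- mixture_model(list(
    spectral_component(1936.8, f, population = 0.5),
    spectral_component(1931.3, f, population = 0.5)), noise_sd = 0)
  tws <- c(1, 8, 16, 24, 32, 40)
  tot <- vapply(tws, function(tw) {
    s <- simulate_2d(m, tw)
    sum(diagonal_projection(s)$absorbance)
  }, 0)
  fit <- lm(log(tot) ~ tws)
  expect_equal(unname(-1 / coef(fit)[2]), 15, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.99999)
})

test_that("reference fixtures carry the published parameterization", {
  wt <- fx_model("wt")
  expect_length(wt$components, 1)
  expect_equal(wt$components[[1]]$population, 1)
  pdx <- fx_model("pdx")
  pops <- vapply(pdx$components, `[[`, 0, "population")
  expect_equal(sort(pops), c(0.25, 0.75))
  lin_area <- vapply(pdx$components, function(cm) cm$population * cm$dipole^2, 0)
  frac <- lin_area / sum(lin_area)
  expect_equal(sort(frac), c(0.35, 0.65), tolerance = 0.01 / 0.35)
  l3 <- fx_model("l358p")
  expect_equal(l3$components[[2]]$nu_0, 1931.2)
  expect_error(p450_fixture("nope"))
})

test_that("pump-probe traces decay with the component lifetime", {
  cm16 <- spectral_component(1939.4, wt_ffcf_ref())
  tr <- simulate_pump_probe(cm16, seq(0, 64, by = 2))
  expect_equal(tr$amplitude[tr$t == 16] / tr$amplitude[1], exp(-1),
               tolerance = 1e-12)
  cm13 <- spectral_component(1931.3, ffcf_params(2.2, 2, 31.7, 1.8,
                                                 t1_lifetime = 13))
  f <- fit_single_exponential(simulate_pump_probe(cm13, seq(0, 60, by = 1.5)))
  expect_equal(f$t1, 13, tolerance = 0.01 / 13)
  # seeded 2% noise: every recovery within half a picosecond
  for (seed in 1:20) {
    trn <- simulate_pump_probe(cm13, seq(0, 60, by = 1.5), seed = seed,
                               noise_sd = 0.02)
    fn <- fit_single_exponential(trn)
    expect_lt(abs(fn$t1 - 13), 0.5)
  }
})

test_that("simulator rejects invalid inputs", {
  m <- fx_model("wt")
  expect_error(simulate_2d(m, -1), "non-negative")
  bad <- mixture_model(list(spectral_component(1902, wt_ffcf_ref())),
                       noise_sd = 0)
  expect_error(simulate_2d(bad, 1), "cover")
  expect_error(simulate_tw_series(m, t_w_list = c(5, 1, 10, 20)), "increasing")
  cmInf <- spectral_component(1939.4, ffcf_params(1.6, 3, 20.7, 4.1))
  expect_error(simulate_pump_probe(cmInf, seq(0, 60, 2)), "finite")
})
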