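# Center-line-slope analysis and FFCF determination.

test_that("center-line slope hits the limiting cases", {
  # (nearly) homogeneous band: horizontal center line
  ph <- suppressWarnings(ffcf_params(3, 0, NA, 0))
  mh <- mixture_model(list(spectral_component(1935, ph)), noise_sd = 0)
  sh <- simulate_2d(mh, 1)
  expect_lt(abs(cls_of(extract_center_line(sh, c(1931, 1939)))["slope"]), 0.02)
  # static-dominated band: slope close to 1
  ps <- ffcf_params(0.25, 0.8, 30, 4.5)
  ms <- mixture_model(list(spectral_component(1935, ps)), noise_sd = 0)
  ss <- simulate_2d(ms, 0.25)
  expect_gt(cls_of(extract_center_line(ss, c(1929, 1941)))["slope"], 0.95)
})

test_that("cls_of is an exact weighted regression", {
  pts <- data.frame(omega3 = seq(1928, 1936, by = 1),
                    omega1_peak = 1000 + 0.65 * seq(1928, 1936, by = 1),
                    weight = rep(1, 9))
  expect_equal(unname(cls_of(pts)["slope"]), 0.65, tolerance = 1e-12)
  set.seed(99)
  slopes <- vapply(1:100, function(i) {
    p <- pts
    p$omega1_peak <- p$omega1_peak + rnorm(9, sd = 0.1)
    unname(cls_of(p)["slope"])
  }, 0)
  expect_lt(abs(mean(slopes) - 0.65), 3 * sd(slopes) / 10)
  expect_error(cls_of(pts[1:3, ]), "5")
})

test_that("the single-component view of the Pdx mixture misreads the dynamics", {
  # treating the composite as one band yields a CLS decay clearly distinct
  # from free wt (slower apparent sampling, inflated static plateau)
  d_wt <- cls_decay(fx_series("wt"))
  d_px <- cls_decay(fx_series("pdx"))
  expect_false(compare_cls(d_wt, d_px)$overlapped)
  expect_gt(d_px$timescale, d_wt$timescale)
})

test_that("wt CLS decay parameters reflect the injected FFCF partition", {
  d <- cls_decay(fx_series("wt"))
  expect_equal(d$timescale, 20.7, tolerance = 0.15)
  expect_equal(d$offset / (d$amplitude + d$offset), 16.81 / 25.81,
               tolerance = 0.05 / 0.651)
})

test_that("a static-only model yields a flat CLS decay", {
  ps <- ffcf_params(1.5, 0.2, 20, 4)
  ms <- mixture_model(list(spectral_component(1936, ps)), noise_sd = 0)
  d <- cls_decay(simulate_tw_series(ms))
  expect_lt(d$amplitude, 0.02)
})

test_that("two identical-FFCF components decay like a single component", {
  f <- ffcf_params(1.6, 3.0, 20.7, 4.1, t1_lifetime = 15)
  m2 <- mixture_model(list(
    spectral_component(1936.8, f, population = 0.5),
    spectral_component(1931.3, f, population = 0.5)), noise_sd = 0)
  m1 <- mixture_model(list(spectral_component(1934, f)), noise_sd = 0)
  d2 <- cls_decay(simulate_tw_series(m2))
  d1 <- cls_decay(simulate_tw_series(m1))
  # the shared FFCF fixes the decay timescale and normalized plateau; the
  # absolute level carries a small offset from the inter-band center-line
  # ramp of the composite
  expect_equal(d2$timescale, d1$timescale, tolerance = 0.15)
  expect_lt(abs(d2$offset / (d2$amplitude + d2$offset) -
                d1$offset / (d1$amplitude + d1$offset)), 0.1)
})

test_that("shrinking the analysis window barely changes the noiseless CLS", {
  s <- fx_series("wt")$spectra[[2]]
  w <- c(1939.4 - 0.6 * 12.9, 1939.4 + 0.6 * 12.9)
  full <- cls_of(extract_center_line(s, w))["slope"]
  w2 <- 1939.4 + 0.75 * (w - 1939.4)
  shrunk <- cls_of(extract_center_line(s, w2))["slope"]
  expect_lt(abs(full - shrunk), 0.02)
})

test_that("the CLS/lineshape co-fit recovers published FFCF rows", {
  d <- cls_decay(fx_series("wt"))
  f <- fit_ffcf(d, fx_linear("wt"), t1_lifetime = 16)
  expect_rel_error(f$gamma_h, 1.6, 0.10)
  expect_rel_error(f$delta_1, 3.0, 0.10)
  expect_rel_error(f$tau_1, 20.7, 0.15)
  expect_rel_error(f$delta_s, 4.1, 0.10)
  # Pdx low band, single-component round trip
  ser_lo <- fx_component_series("pdx", 2)
  lin_lo <- synth_linear(spectral_component(1931.3, ffcf_params(2.2, 2, 31.7, 1.8)),
                         seq(1900, 1970, by = 0.25))
  f2 <- fit_ffcf(cls_decay(ser_lo), lin_lo, t1_lifetime = 13)
  expect_rel_error(f2$gamma_h, 2.2, 0.10)
  expect_rel_error(f2$delta_1, 2.0, 0.10)
  expect_rel_error(f2$tau_1, 31.7, 0.15)
  expect_rel_error(f2$delta_s, 1.8, 0.10)
})

test_that("a homogeneous-only band maps to a pure Lorentzian FFCF", {
  ph <- suppressWarnings(ffcf_params(6, 0.15, 15, 0.15))
  mh <- mixture_model(list(spectral_component(1935, ph)), noise_sd = 0)
  ser <- simulate_tw_series(mh)
  lin <- synth_linear_mixture(mh)
  d <- cls_decay(ser)
  f <- fit_ffcf(d, lin)
  expect_equal(f$gamma_h, fwhm_of(lin), tolerance = 0.02)
  expect_lt(sqrt(f$delta_1^2 + f$delta_s^2), 0.6)
})

test_that("simulate/fit round trips recover random quasi-static FFCFs", {
  set.seed(505)
  ax <- seq(1900, 1970, by = 0.25)
  for (i in 1:8) {
    repeat {
      gh <- runif(1, 0.8, 3); d1 <- runif(1, 1.2, 3.2)
      tau <- runif(1, 12, 34); ds <- runif(1, 1.2, 4)
      p <- ffcf_params(gh, d1, tau, ds, t1_lifetime = 15)
      if (motional_narrowing(p) > 5) break
    }
    m <- mixture_model(list(spectral_component(1936, p)), noise_sd = 0)
    f <- fit_ffcf(cls_decay(simulate_tw_series(m)),
                  synth_linear_mixture(m), t1_lifetime = 15)
    expect_rel_error(f$gamma_h, gh, 0.15)
    expect_rel_error(f$delta_1, d1, 0.15)
    expect_rel_error(f$tau_1, tau, 0.15)
    expect_rel_error(f$delta_s, ds, 0.15)
  }
})

test_that("decay containers validate their contracts", {
  expect_warning(cls_decay_from_slopes(c(1, 5, 10, 20), c(1.2, 0.5, 0.4, 0.3)),
                 "outside")
  d <- cls_decay_from_slopes(c(0.25, 5, 15, 30, 44),
                             0.4 * exp(-c(0.25, 5, 15, 30, 44) / 20) + 0.3)
  expect_equal(d$timescale, 20, tolerance = 0.02)
  expect_equal(d$offset, 0.3, tolerance = 0.01)
})
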