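# Kubo-model machinery: FFCF evaluation, lineshape function, linear spectra.

test_that("inhomogeneous FFCF evaluates the two-timescale model", {
  wt <- wt_ffcf_ref()
  expect_equal(ffcf_inhomogeneous(wt, 0), 3.0^2 + 4.1^2)
  expect_equal(ffcf_inhomogeneous(wt, 1e6), 4.1^2, tolerance = 1e-10)
  expect_equal(ffcf_inhomogeneous(wt, 20.7), 9 * exp(-1) + 16.81,
               tolerance = 1e-10)
  expect_error(ffcf_inhomogeneous(wt, -1), "non-negative")
})

test_that("inhomogeneous FFCF matches the covariance of an OU frequency trajectory", {
  # independent oracle: discrete Ornstein-Uhlenbeck trajectory with the wt
  # amplitude/timescale plus a static frozen offset
  set.seed(42)
  d1 <- 3.0; tau <- 20.7; ds <- 4.1
  dt <- 0.25; nstep <- 4e5
  phi <- exp(-dt / tau)
  eps <- rnorm(nstep, sd = d1 * sqrt(1 - phi^2))
  x <- numeric(nstep); x[1] <- rnorm(1, sd = d1)
  for (i in 2:nstep) x[i] <- phi * x[i - 1] + eps[i]
  lag <- round(20.7 / dt)
  cov_ou <- mean(x[1:(nstep - lag)] * x[(1 + lag):nstep])
  oracle <- cov_ou + ds^2   # static term adds a constant offset
  expect_equal(ffcf_inhomogeneous(wt_ffcf_ref(), 20.7), oracle,
               tolerance = 0.03)
})

test_that("FFCF is monotone non-increasing and bounded", {
  set.seed(7)
  for (i in 1:12) {
    p <- suppressWarnings(
      ffcf_params(runif(1, 0.5, 4), runif(1, 0.5, 4), runif(1, 5, 50),
                  runif(1, 0, 4)))
    t <- sort(runif(30, 0, 100))
    v <- ffcf_inhomogeneous(p, t)
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(v <= p$delta_1^2 + p$delta_s^2 + 1e-12))
    expect_true(all(v >= p$delta_s^2 - 1e-12))
  }
})

test_that("lineshape function matches the double-integral quadrature oracle", {
  # g(t) should equal the double time-integral of the (angular-frequency)
  # FFCF plus the homogeneous linear term
  g_oracle <- function(p, tmax, npts = 1e4) {
    tt <- seq(0, tmax, length.out = npts)
    c_cmps <- 2.99792458e-2
    C <- (2 * pi * c_cmps)^2 * ffcf_inhomogeneous(p, tt)
    inner <- cumsum((C[-1] + C[-npts]) / 2) * diff(tt)[1]
    inner <- c(0, inner)
    outer_int <- cumsum((inner[-1] + inner[-npts]) / 2) * diff(tt)[1]
    outer_int <- c(0, outer_int)
    outer_int + pi * c_cmps * p$gamma_h * tt
  }
  for (p in list(wt_ffcf_ref(),
                 ffcf_params(2.2, 2.0, 31.7, 1.8),
                 suppressWarnings(ffcf_params(1.0, 1.5, 8, 0)))) {
    tt <- seq(0, 100, length.out = 1e4)
    g <- Re(lineshape_g(p, tt))
    go <- g_oracle(p, 100)
    expect_lt(max(abs(g[-1] - go[-1]) / pmax(go[-1], 1e-12)), 1e-4)
  }
  expect_equal(Re(lineshape_g(wt_ffcf_ref(), 0)), 0)
  # homogeneous limit: purely linear in t
  ph <- suppressWarnings(ffcf_params(2, 0, NA, 0))
  tt <- seq(0, 50, by = 0.5)
  expect_equal(Re(lineshape_g(ph, tt)), pi * 2.99792458e-2 * 2 * tt,
               tolerance = 1e-12)
  expect_error(lineshape_g(wt_ffcf_ref(), c(1, 0.5)), "non-decreasing")
})

test_that("random lineshape draws agree with the quadrature oracle", {
  set.seed(11)
  c_cmps <- 2.99792458e-2
  for (i in 1:20) {
    p <- suppressWarnings(
      ffcf_params(runif(1, 0.5, 3), runif(1, 0.5, 3.5), runif(1, 8, 40),
                  runif(1, 0.2, 4)))
    tt <- seq(0, 60, length.out = 4000)
    C <- (2 * pi * c_cmps)^2 * ffcf_inhomogeneous(p, tt)
    inner <- c(0, cumsum((C[-1] + C[-4000]) / 2) * diff(tt)[1])
    oo <- c(0, cumsum((inner[-1] + inner[-4000]) / 2) * diff(tt)[1]) +
      pi * c_cmps * p$gamma_h * tt
    g <- Re(lineshape_g(p, tt))
    expect_lt(max(abs(g[-1] - oo[-1]) / pmax(oo[-1], 1e-10)), 1e-4)
  }
})

test_that("synthesized linear lineshapes reproduce the reported bandwidths", {
  ax <- seq(1880, 2000, by = 0.05)
  wt <- synth_linear(wt_ffcf_ref(), ax, nu_0 = 1939.4)
  expect_equal(fwhm_of(wt), 12.9, tolerance = 0.5 / 12.9)
  lo <- synth_linear(ffcf_params(2.2, 2.0, 31.7, 1.8), ax, nu_0 = 1931.3)
  expect_equal(fwhm_of(lo), 7.6, tolerance = 0.3 / 7.6)
  # peak within one grid step of the band center
  expect_lt(abs(wt$wavenumber[which.max(wt$absorbance)] - 1939.4), 0.06)
})

test_that("homogeneous limit gives a Lorentzian of the requested width", {
  ax <- seq(1900, 1970, by = 0.02)
  ph <- suppressWarnings(ffcf_params(2, 0, NA, 0))
  s <- synth_linear(ph, ax, nu_0 = 1935)
  expect_equal(fwhm_of(s), 2.0, tolerance = 0.01)
  # Lorentzian shape check at one off-center point
  y0 <- max(s$absorbance)
  y1 <- approx(s$wavenumber, s$absorbance, xout = 1935 + 1)$y
  expect_equal(y1 / y0, 1 / (1 + (1 / 1)^2), tolerance = 0.02)
})

test_that("linear band area scales with population and dipole squared", {
  ax <- seq(1880, 2000, by = 0.1)
  area <- function(pop, dip) {
    cm <- spectral_component(1939.4, wt_ffcf_ref(), dipole = dip,
                             population = pop)
    s <- synth_linear(cm, ax)
    sum(s$absorbance) * 0.1
  }
  a0 <- area(1, 1)
  for (pop in c(0.2, 0.5, 0.8))
    expect_equal(area(pop, 1) / a0, pop, tolerance = 1e-6)
  for (dip in c(0.8, 1.27, 1.6))
    expect_equal(area(1, dip) / a0, dip^2, tolerance = 1e-6)
})

test_that("synth_linear width agrees with the Voigt prediction in the quasi-static regime", {
  ax <- seq(1860, 2020, by = 0.05)
  for (p in list(wt_ffcf_ref(), ffcf_params(2.2, 2.0, 31.7, 1.8),
                 ffcf_params(3.4, 2.6, 30.5, 2.5))) {
    expect_gt(motional_narrowing(p), 5)
    gw <- 2 * sqrt(2 * log(2)) * sqrt(p$delta_1^2 + p$delta_s^2)
    pred <- voigt_fwhm(gw, p$gamma_h)
    got <- fwhm_of(synth_linear(p, ax, nu_0 = 1939.4))
    expect_equal(got, pred, tolerance = 0.02)
  }
})

test_that("voigt_fwhm matches a numerical convolution", {
  expect_equal(voigt_fwhm(5, 0), 5, tolerance = 1e-4)
  expect_equal(voigt_fwhm(0, 3), 3, tolerance = 1e-4)
  expect_error(voigt_fwhm(0, 0), "both")
  # dense-grid numerical convolution oracle
  dx <- 0.005
  x <- seq(-150, 150, by = dx)
  G <- exp(-4 * log(2) * x^2 / 11.96^2)
  L <- (1.6 / 2)^2 / (x^2 + (1.6 / 2)^2)
  V <- Re(fft(fft(G) * fft(L), inverse = TRUE))
  V <- c(V[(length(V) / 2 + 1):length(V)], V[1:(length(V) / 2)])
  num <- fwhm_of(x, V)
  expect_equal(voigt_fwhm(11.96, 1.6), num, tolerance = 0.002)
  expect_equal(num, 12.85, tolerance = 0.02 / 12.85)
})

test_that("fwhm_of recovers known widths by interpolation", {
  x <- seq(-50, 50, by = 0.1)
  g <- exp(-4 * log(2) * x^2 / 8.5^2)
  expect_equal(fwhm_of(x + 1935, g), 8.5, tolerance = 0.01 / 8.5)
  l <- 1 / (1 + (x / (3.4 / 2))^2)
  expect_equal(fwhm_of(x + 1935, l), 3.4, tolerance = 0.01 / 3.4)
  # composite of two Gaussians vs brute-force dense grid scan
  h1 <- 0.65 / 7.6; h2 <- 0.35 / 8.6
  comp <- function(xx) h1 * exp(-4 * log(2) * (xx - 1931.3)^2 / 7.6^2) +
    h2 * exp(-4 * log(2) * (xx - 1936.8)^2 / 8.6^2)
  xx <- seq(1900, 1970, by = 0.1)
  xf <- seq(1900, 1970, by = 0.001)
  yf <- comp(xf)
  half <- max(yf) / 2
  oracle <- diff(range(xf[yf >= half]))
  expect_equal(fwhm_of(xx, comp(xx)), oracle, tolerance = 0.01)
  expect_error(fwhm_of(x[x < 1], g[x < 1]), "edge|crossed")
})

test_that("constructors validate their invariants", {
  expect_error(ffcf_params(-1, 1, 10, 1), "gamma_h")
  expect_error(ffcf_params(1, 2, NA, 1), "tau_1")
  expect_warning(ffcf_params(1, 0.5, 0.5, 1), "not separable")
  expect_error(spectral_component(1939, wt_ffcf_ref(), population = 1.2),
               "population")
  expect_error(linear_spectrum(1:20, 1:19), "equal length")
  expect_error(linear_spectrum(c(1:19, 19), 1:20), "increasing")
  expect_error(synth_linear(wt_ffcf_ref(), seq(1930, 1950, 0.5),
                            nu_0 = 1939.4), "narrow")
  # derived T2* is finite and positive
  expect_gt(1 / (pi * 2.99792458e-2 * wt_ffcf_ref()$gamma_h), 0)
})

test_that("first_moment computes amplitude-weighted means", {
  x <- seq(1900, 1970, by = 0.25)
  g <- exp(-4 * log(2) * (x - 1934.2)^2 / 8^2)
  expect_equal(first_moment(linear_spectrum(x, g)), 1934.2, tolerance = 0.05)
  # two delta-like bands of equal weight
  y <- dnorm(x, 1931.3, 0.15) + dnorm(x, 1936.8, 0.15)
  expect_equal(first_moment(linear_spectrum(x, y)), 1934.05, tolerance = 0.01)
  expect_error(first_moment(linear_spectrum(x, g), window = c(1890, 1920)),
               "outside|weight")
})
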