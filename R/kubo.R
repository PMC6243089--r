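#' Kubo-model FFCF parameter set
#'
#' Bundles the parameters of the frequency-frequency correlation function
#' (FFCF) used throughout the package,
#' \deqn{C(t) = \frac{\delta(t)}{T_2^*} + \Delta_1^2 e^{-t/\tau_1} + \Delta_s^2,}
#' i.e. a motionally narrowed homogeneous term (Lorentzian FWHM
#' \eqn{\Gamma^* = 1/(\pi c T_2^*)}), one exponentially sampled inhomogeneous
#' term, and a static inhomogeneous term describing dynamics slower than the
#' experimental window.
#'
#' `gamma_h` is interpreted as the *total* homogeneous Lorentzian FWHM,
#' including the vibrational-lifetime contribution; lifetime decay is applied
#' separately, and only to waiting-time population relaxation, by the 2D
#' simulator (see the package vignette for the rationale).
#'
#' When the motional-narrowing product \eqn{2\pi c \Delta_1 \tau_1 < 1} the
#' amplitude and timescale of the fast term are not separable from the
#' lineshape; a warning marks the pair as non-identifiable.
#'
#' @param gamma_h homogeneous Lorentzian FWHM \eqn{\Gamma^*} (cm\eqn{^{-1}}),
#'   > 0.
#' @param delta_1 amplitude of the exponentially sampled inhomogeneous term
#'   \eqn{\Delta_1} (cm\eqn{^{-1}}), >= 0.
#' @param tau_1 sampling timescale \eqn{\tau_1} (ps); required > 0 when
#'   `delta_1 > 0`, ignored otherwise.
#' @param delta_s static inhomogeneous amplitude \eqn{\Delta_s}
#'   (cm\eqn{^{-1}}), >= 0.
#' @param t1_lifetime vibrational lifetime \eqn{T_1} (ps); `Inf` means no
#'   population relaxation.
#' @return An object of class `"ffcf_params"`.
#' @examples
#' wt <- ffcf_params(gamma_h = 1.6, delta_1 = 3.0, tau_1 = 20.7, delta_s = 4.1,
#'                   t1_lifetime = 16)
#' ffcf_inhomogeneous(wt, t = 0)     # 3^2 + 4.1^2
#' @seealso [ffcf_inhomogeneous()], [lineshape_g()], [synth_linear()]
#' @export
ffcf_params <- function(gamma_h, delta_1, tau_1 = NA_real_, delta_s = 0,
                        t1_lifetime = Inf) {
  stopifnot(is.numeric(gamma_h), length(gamma_h) == 1, is.finite(gamma_h),
            is.numeric(delta_1), length(delta_1) == 1, is.finite(delta_1),
            is.numeric(delta_s), length(delta_s) == 1, is.finite(delta_s))
  if (gamma_h <= 0) stop("'gamma_h' must be > 0")
  if (delta_1 < 0 || delta_s < 0) stop("'delta_1' and 'delta_s' must be >= 0")
  if (delta_1 > 0) {
    if (!is.finite(tau_1) || tau_1 <= 0)
      stop("'tau_1' must be > 0 when delta_1 > 0")
  } else {
    tau_1 <- NA_real_
  }
  if (!(is.numeric(t1_lifetime) && length(t1_lifetime) == 1 &&
        (is.infinite(t1_lifetime) || t1_lifetime > 0)))
    stop("'t1_lifetime' must be a positive number or Inf")
  p <- structure(list(gamma_h = gamma_h, delta_1 = delta_1, tau_1 = tau_1,
                      delta_s = delta_s, t1_lifetime = t1_lifetime),
                 class = "ffcf_params")
  mn <- motional_narrowing(p)
  if (!is.na(mn) && mn < 1)
    warning(sprintf(paste0("motional-narrowing product 2*pi*c*delta_1*tau_1 = %.3g < 1: ",
                           "delta_1 and tau_1 are not separable from the lineshape"), mn))
  p
}

#' @export
print.ffcf_params <- function(x, ...) {
  cat("Kubo FFCF parameters\n")
  cat(sprintf("  Gamma* (homogeneous FWHM): %.3g cm-1  (T2* = %.3g ps)\n",
              x$gamma_h, 1 / (pi * .c_cmps * x$gamma_h)))
  cat(sprintf("  Delta_1: %.3g cm-1   tau_1: %.3g ps\n", x$delta_1, x$tau_1))
  cat(sprintf("  Delta_s: %.3g cm-1   T1: %.3g ps\n", x$delta_s, x$t1_lifetime))
  invisible(x)
}

#' Motional-narrowing diagnostic
#'
#' The dimensionless product \eqn{2\pi c \Delta_1 \tau_1}. Values well below 1
#' put the fast inhomogeneous term in the motionally narrowed limit where its
#' amplitude and timescale cannot be determined independently; values above ~5
#' indicate the quasi-static regime in which \eqn{\Delta_1} contributes
#' Gaussian broadening.
#'
#' @param params an [ffcf_params()] object.
#' @return The product (NA when `delta_1 == 0`).
#' @export
motional_narrowing <- function(params) {
  stopifnot(inherits(params, "ffcf_params"))
  if (params$delta_1 == 0) return(NA_real_)
  .twopic * params$delta_1 * params$tau_1
}

#' Inhomogeneous part of the FFCF
#'
#' Evaluates \eqn{\Delta_1^2 e^{-t/\tau_1} + \Delta_s^2} in cm\eqn{^{-2}}.
#' Monotone non-increasing in `t`, bounded between \eqn{\Delta_s^2} and
#' \eqn{\Delta_1^2 + \Delta_s^2}.
#'
#' @param params an [ffcf_params()] object.
#' @param t time(s) in ps, >= 0.
#' @return Correlation values (cm\eqn{^{-2}}), same length as `t`.
#' @export
ffcf_inhomogeneous <- function(params, t) {
  stopifnot(inherits(params, "ffcf_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  out <- rep(params$delta_s^2, length(t))
  if (params$delta_1 > 0)
    out <- out + params$delta_1^2 * exp(-t / params$tau_1)
  out
}

# scalar/vector/matrix-safe g(t); internal, no class checks
.kubo_g <- function(t, gamma_h, delta_1, tau_1, delta_s) {
  Ds <- .twopic * delta_s
  out <- Ds^2 * t^2 / 2 + pi * .c_cmps * gamma_h * t
  if (delta_1 > 0) {
    D1 <- .twopic * delta_1
    out <- out + D1^2 * tau_1^2 * (exp(-t / tau_1) + t / tau_1 - 1)
  }
  out
}

#' Second-cumulant lineshape function g(t)
#'
#' The lineshape function corresponding to the Kubo FFCF,
#' \deqn{g(t) = \Delta_1^2 \tau_1^2 (e^{-t/\tau_1} + t/\tau_1 - 1)
#'       + \Delta_s^2 t^2/2 + \pi c \Gamma^* t,}
#' with \eqn{\Delta_1, \Delta_s} converted from cm\eqn{^{-1}} to rad/ps via
#' \eqn{2\pi c} before use. Linear and 2D spectra follow from \eqn{e^{-g(t)}}
#' by Fourier transformation. `g(0) = 0` and the real part is convex
#' increasing.
#'
#' @param params an [ffcf_params()] object.
#' @param t_grid non-negative, non-decreasing times (ps).
#' @return Complex vector of g values (imaginary part zero for this FFCF; the
#'   complex type is kept for generality of downstream Fourier code).
#' @export
lineshape_g <- function(params, t_grid) {
  stopifnot(inherits(params, "ffcf_params"), is.numeric(t_grid))
  if (any(t_grid < 0)) stop("'t_grid' must be non-negative")
  if (is.unsorted(t_grid)) stop("'t_grid' must be non-decreasing")
  as.complex(.kubo_g(t_grid, params$gamma_h, params$delta_1, params$tau_1,
                     params$delta_s))
}

#' One spectral component of a vibrational probe
#'
#' A conformational state's band: center frequency, Kubo FFCF, relative
#' transition dipole magnitude and fractional population. The simulator
#' enforces the intensity rules: linear band area scales as
#' `population * dipole^2`, 2D band amplitude as `population * dipole^4`.
#'
#' @param nu_0 band center (cm\eqn{^{-1}}).
#' @param ffcf an [ffcf_params()] object.
#' @param dipole relative transition dipole magnitude (> 0; reference
#'   component = 1).
#' @param population fractional occupancy in \[0, 1\].
#' @return An object of class `"spectral_component"`.
#' @export
spectral_component <- function(nu_0, ffcf, dipole = 1, population = 1) {
  stopifnot(is.numeric(nu_0), length(nu_0) == 1, is.finite(nu_0),
            inherits(ffcf, "ffcf_params"))
  if (dipole <= 0) stop("'dipole' must be > 0")
  if (population < 0 || population > 1) stop("'population' must be in [0, 1]")
  structure(list(nu_0 = nu_0, ffcf = ffcf, dipole = dipole,
                 population = population),
            class = "spectral_component")
}

#' @export
print.spectral_component <- function(x, ...) {
  cat(sprintf("Spectral component at %.1f cm-1 (population %.3g, dipole %.3g)\n",
              x$nu_0, x$population, x$dipole))
  print(x$ffcf)
  invisible(x)
}

#' Linear absorption spectrum container
#'
#' A 1D spectrum on a strictly increasing, uniformly spaced wavenumber axis.
#'
#' @param wavenumber axis in cm\eqn{^{-1}}, length >= 16, uniform spacing to
#'   within 1 part in 1e6.
#' @param absorbance values (arbitrary units), same length as the axis.
#' @return An object of class `"linear_spectrum"` (a list with elements
#'   `wavenumber` and `absorbance`).
#' @export
linear_spectrum <- function(wavenumber, absorbance) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance))
  if (length(wavenumber) < 16) stop("axis must have at least 16 points")
  if (length(wavenumber) != length(absorbance))
    stop("axis and absorbance must have equal length")
  d <- diff(wavenumber)
  if (any(d <= 0)) stop("axis must be strictly increasing")
  if ((max(d) - min(d)) / mean(d) > 1e-6)
    stop("axis spacing must be uniform to within 1 part in 1e6")
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance)),
            class = "linear_spectrum")
}

#' @export
print.linear_spectrum <- function(x, ...) {
  cat(sprintf("Linear spectrum: %d points, %.2f-%.2f cm-1 (step %.4g)\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              diff(x$wavenumber)[1]))
  invisible(x)
}

#' @export
plot.linear_spectrum <- function(x, ..., xlab = expression(omega / cm^-1),
                                 ylab = "absorbance", type = "l") {
  plot(x$wavenumber, x$absorbance, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Full width at half maximum of a spectrum
#'
#' Locates the half-maximum crossings on either side of the unique global
#' maximum by linear interpolation and returns their separation.
#'
#' @param spectrum a [linear_spectrum()], or a numeric axis when `y` is given.
#' @param y absorbance values when `spectrum` is a plain numeric axis.
#' @return FWHM in axis units.
#' @export
fwhm_of <- function(spectrum, y = NULL) {
  if (inherits(spectrum, "linear_spectrum")) {
    x <- spectrum$wavenumber; yy <- spectrum$absorbance
  } else {
    x <- spectrum; yy <- y
  }
  i <- which.max(yy)
  if (i == 1 || i == length(yy)) stop("maximum lies at an axis edge")
  if (sum(yy == yy[i]) > 1) i <- round(mean(which(yy == yy[i])))
  h <- yy[i] / 2
  left <- which(yy[1:i] <= h)
  right <- which(yy[i:length(yy)] <= h)
  if (length(left) == 0 || length(right) == 0)
    stop("half maximum not crossed on both sides of the peak")
  lo <- max(left); hi <- i - 1 + min(right)
  xl <- x[lo] + (h - yy[lo]) / (yy[lo + 1] - yy[lo]) * (x[lo + 1] - x[lo])
  xr <- x[hi - 1] + (h - yy[hi - 1]) / (yy[hi] - yy[hi - 1]) * (x[hi] - x[hi - 1])
  xr - xl
}

#' Voigt profile FWHM (Olivero-Longbothum approximation)
#'
#' Accurate to about 0.02% of the numerically computed convolution width;
#' used for fit initialisation and cross-checks.
#'
#' @param gaussian_fwhm Gaussian FWHM (>= 0).
#' @param lorentzian_fwhm Lorentzian FWHM (>= 0); not both zero.
#' @return Approximate Voigt FWHM.
#' @export
voigt_fwhm <- function(gaussian_fwhm, lorentzian_fwhm) {
  if (any(gaussian_fwhm < 0) || any(lorentzian_fwhm < 0))
    stop("widths must be >= 0")
  if (any(gaussian_fwhm == 0 & lorentzian_fwhm == 0))
    stop("Gaussian and Lorentzian widths cannot both be zero")
  0.5346 * lorentzian_fwhm +
    sqrt(0.2166 * lorentzian_fwhm^2 + gaussian_fwhm^2)
}

# shared FT of exp(-g(t)) onto a wavenumber axis centered at nu_0.
# Design: dt <= 0.05 ps, extent >= 20x the slowest coherence decay, cosine
# half-apodization over the final 10%, zero padding to >= 4x sample count.
.kubo_lineshape_ft <- function(ffcf, nu_0, axis, include_lifetime = FALSE) {
  T2 <- 1 / (pi * .c_cmps * ffcf$gamma_h)
  # the homogeneous coherence is the slowest decay for realistic parameters;
  # 40 ps floor keeps narrow-band resolution when gamma_h is large
  tmax <- max(20 * T2, 40)
  dt <- 0.05
  n <- ceiling(tmax / dt) + 1
  t <- (0:(n - 1)) * dt
  g <- .kubo_g(t, ffcf$gamma_h, ffcf$delta_1, ffcf$tau_1, ffcf$delta_s)
  E <- exp(-g)
  if (include_lifetime && is.finite(ffcf$t1_lifetime))
    E <- E * exp(-t / (2 * ffcf$t1_lifetime))
  i0 <- floor(0.9 * n); idx <- i0:n
  w <- rep(1, n)
  w[idx] <- 0.5 * (1 + cos(pi * (idx - i0) / (n - i0)))
  E <- E * w
  E[1] <- E[1] / 2
  np <- 2^ceiling(log2(4 * n))
  S <- Re(fft(c(E, rep(0, np - n)), inverse = TRUE)) * dt
  k <- 0:(np - 1)
  nu_rel <- k / (np * dt * .c_cmps)
  wrap <- k >= np / 2
  nu_rel[wrap] <- nu_rel[wrap] - 1 / (dt * .c_cmps)
  ord <- order(nu_rel)
  approx(nu_0 + nu_rel[ord], S[ord], xout = axis)$y
}

#' Synthesize a linear absorption spectrum from Kubo parameters
#'
#' Computes \eqn{A(\omega) \propto \mathrm{Re}\int_0^\infty
#' e^{i(\omega-\omega_0)t} e^{-g(t)} dt} on the requested axis. Because
#' `gamma_h` is the total homogeneous FWHM, no separate lifetime factor is
#' applied. The integrated area is scaled to `population * dipole^2`.
#'
#' @param component a [spectral_component()] (or an [ffcf_params()], in which
#'   case `nu_0` must be given and unit population/dipole are used).
#' @param axis wavenumber grid; must extend at least two expected FWHM beyond
#'   the band center on both sides.
#' @param nu_0 band center when `component` is a bare parameter set.
#' @return A [linear_spectrum()].
#' @export
synth_linear <- function(component, axis, nu_0 = NULL) {
  if (inherits(component, "ffcf_params")) {
    stopifnot(!is.null(nu_0))
    component <- spectral_component(nu_0, component)
  }
  stopifnot(inherits(component, "spectral_component"))
  ffcf <- component$ffcf
  gw <- 2 * sqrt(2 * log(2)) * sqrt(ffcf$delta_1^2 + ffcf$delta_s^2)
  fw_exp <- if (gw == 0) ffcf$gamma_h else voigt_fwhm(gw, ffcf$gamma_h)
  if (component$nu_0 - min(axis) < 2 * fw_exp ||
      max(axis) - component$nu_0 < 2 * fw_exp)
    stop("axis too narrow: band center within 2 FWHM of an edge")
  yv <- .kubo_lineshape_ft(ffcf, component$nu_0, axis)
  yv <- pmax(yv, 0)
  area <- sum(yv) * mean(diff(axis))
  yv <- yv / area * component$population * component$dipole^2
  linear_spectrum(axis, yv)
}

#' Amplitude-weighted first moment of a spectrum
#'
#' @param spectrum a [linear_spectrum()].
#' @param window optional `c(lo, hi)` wavenumber window (default: full axis).
#' @return The weighted mean frequency (cm\eqn{^{-1}}).
#' @export
first_moment <- function(spectrum, window = NULL) {
  stopifnot(inherits(spectrum, "linear_spectrum"))
  x <- spectrum$wavenumber; yv <- spectrum$absorbance
  if (!is.null(window)) {
    if (window[1] < min(x) || window[2] > max(x))
      stop("window outside the spectrum axis")
    k <- x >= window[1] & x <= window[2]
    x <- x[k]; yv <- yv[k]
  }
  tot <- sum(yv)
  if (!is.finite(tot) || tot <= 0) stop("non-positive total weight in window")
  sum(x * yv) / tot
}
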