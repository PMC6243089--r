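#' Purely absorptive 2D IR spectrum at one waiting time
#'
#' @param omega1 pump axis (cm\eqn{^{-1}}), strictly increasing, uniform.
#' @param omega3 probe axis (cm\eqn{^{-1}}), strictly increasing, uniform.
#' @param t_w waiting time (ps), >= 0.
#' @param amplitude real matrix with `length(omega1)` rows and
#'   `length(omega3)` columns; column `j` is the pump-axis profile detected at
#'   `omega3[j]`.
#' @return An object of class `"spectrum2d"`.
#' @export
spectrum2d <- function(omega1, omega3, t_w, amplitude) {
  .check_axis(omega1, "omega1"); .check_axis(omega3, "omega3")
  stopifnot(is.matrix(amplitude), is.numeric(amplitude))
  if (nrow(amplitude) != length(omega1) || ncol(amplitude) != length(omega3))
    stop("amplitude dimensions must match the axes (omega1 rows, omega3 columns)")
  if (!is.numeric(t_w) || length(t_w) != 1 || t_w < 0)
    stop("'t_w' must be a single non-negative waiting time")
  structure(list(omega1 = as.numeric(omega1), omega3 = as.numeric(omega3),
                 t_w = t_w, amplitude = amplitude),
            class = "spectrum2d")
}

.check_axis <- function(x, name) {
  d <- diff(x)
  if (length(x) < 8 || any(d <= 0) || (max(d) - min(d)) / mean(d) > 1e-6)
    stop(sprintf("'%s' must be strictly increasing and uniformly spaced", name))
  invisible(x)
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("2D IR spectrum at Tw = %.3g ps: %d x %d (omega1 %.1f-%.1f, omega3 %.1f-%.1f cm-1)\n",
              x$t_w, length(x$omega1), length(x$omega3),
              min(x$omega1), max(x$omega1), min(x$omega3), max(x$omega3)))
  invisible(x)
}

#' @export
plot.spectrum2d <- function(x, nlevels = 20, ...) {
  image(x$omega1, x$omega3, x$amplitude,
        col = hcl.colors(64, "RdBu", rev = TRUE),
        xlab = expression(omega[1] / cm^-1), ylab = expression(omega[3] / cm^-1),
        main = sprintf("Tw = %.3g ps", x$t_w), ...)
  contour(x$omega1, x$omega3, x$amplitude, nlevels = nlevels, add = TRUE,
          drawlabels = FALSE)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Waiting-time series of 2D spectra
#'
#' @param spectra list of [spectrum2d()] objects with identical axes and
#'   strictly increasing waiting times.
#' @return An object of class `"tw_series2d"`.
#' @export
tw_series <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "spectrum2d")))
  tws <- vapply(spectra, `[[`, 0, "t_w")
  if (any(diff(tws) <= 0)) stop("waiting times must be strictly increasing")
  a1 <- spectra[[1]]$omega1; a3 <- spectra[[1]]$omega3
  same <- vapply(spectra, function(s)
    isTRUE(all.equal(s$omega1, a1)) && isTRUE(all.equal(s$omega3, a3)), TRUE)
  if (!all(same)) stop("all spectra must share identical axes")
  structure(list(spectra = spectra, t_w = tws, omega1 = a1, omega3 = a3),
            class = "tw_series2d")
}

#' @export
print.tw_series2d <- function(x, ...) {
  cat(sprintf("2D IR waiting-time series: %d frames, Tw = %s ps\n",
              length(x$spectra), paste(signif(x$t_w, 3), collapse = ", ")))
  invisible(x)
}

#' @export
length.tw_series2d <- function(x) length(x$spectra)

# bilinear interpolation of a spectrum2d amplitude at arbitrary points
.interp2 <- function(spec, x1, x3) {
  a1 <- spec$omega1; a3 <- spec$omega3; S <- spec$amplitude
  r1 <- pmin(pmax(findInterval(x1, a1), 1), length(a1) - 1)
  r3 <- pmin(pmax(findInterval(x3, a3), 1), length(a3) - 1)
  d1 <- (x1 - a1[r1]) / (a1[r1 + 1] - a1[r1])
  d3 <- (x3 - a3[r3]) / (a3[r3 + 1] - a3[r3])
  S[cbind(r1, r3)] * (1 - d1) * (1 - d3) +
    S[cbind(r1 + 1, r3)] * d1 * (1 - d3) +
    S[cbind(r1, r3 + 1)] * (1 - d1) * d3 +
    S[cbind(r1 + 1, r3 + 1)] * d1 * d3
}

#' Diagonal slice through a 2D spectrum
#'
#' Interpolates the amplitude along \eqn{\omega_1 = \omega_3} over the shared
#' axis range. Because 2D intensity scales with the fourth power of the
#' transition dipole (vs the square for linear absorption), strong-dipole
#' components are accentuated in the diagonal slice relative to the linear
#' spectrum.
#'
#' @param spec2d a [spectrum2d()].
#' @param step sampling step of the slice (default: the omega3 grid step).
#' @return A [linear_spectrum()] sampled along the diagonal.
#' @export
diagonal_slice <- function(spec2d, step = NULL) {
  stopifnot(inherits(spec2d, "spectrum2d"))
  lo <- max(min(spec2d$omega1), min(spec2d$omega3))
  hi <- min(max(spec2d$omega1), max(spec2d$omega3))
  if (hi <= lo) stop("omega1 and omega3 axes do not overlap")
  if (is.null(step)) step <- mean(diff(spec2d$omega3))
  nu <- seq(lo, hi, by = step)
  linear_spectrum(nu, .interp2(spec2d, nu, nu))
}

#' Pump-axis projection of the fundamental 2D band
#'
#' Integrates the amplitude over the probe axis restricted to the fundamental
#' (0-1) region, excluding the anharmonically shifted excited-state
#' absorption. For the response functions used by the simulator this marginal
#' has two exact properties that the diagonal slice lacks: a component's
#' projected band area is strictly proportional to
#' `population * dipole^4 * exp(-Tw/T1)`, and its shape equals the component's
#' linear lineshape at every waiting time. The projection is therefore the
#' preferred trace for quantitative band-area work (dipole ratios, global
#' lifetime fits); the diagonal slice remains the natural display and
#' first-moment diagnostic.
#'
#' @param spec2d a [spectrum2d()].
#' @param cut lower bound of the probe-axis window (cm\eqn{^{-1}}); defaults
#'   to one quarter of the axis span above the axis minimum, which excludes
#'   the excited-state band for the default simulation grids.
#' @return A [linear_spectrum()] on the pump axis.
#' @export
diagonal_projection <- function(spec2d, cut = NULL) {
  stopifnot(inherits(spec2d, "spectrum2d"))
  a3 <- spec2d$omega3
  if (is.null(cut)) cut <- min(a3) + 0.25 * diff(range(a3))
  k <- a3 >= cut
  if (sum(k) < 4) stop("probe-axis window above 'cut' is too small")
  p <- rowSums(spec2d$amplitude[, k, drop = FALSE]) * mean(diff(a3))
  linear_spectrum(spec2d$omega1, p)
}
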