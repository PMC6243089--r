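# Center-line-slope analysis: center-line extraction, CLS decays, and FFCF
# determination by co-fitting the CLS decay with the linear spectrum.

#' Extract the center line from a 2D spectrum
#'
#' For each probe frequency \eqn{\omega_3} in the window, locates the pump
#' frequency of maximum amplitude by fitting a parabola to the five points
#' bracketing the discrete maximum (sub-grid precision). Points whose
#' discrete maximum lies within two grid steps of the pump-axis edge are
#' dropped. Each surviving point carries the slice peak amplitude as its
#' weight.
#'
#' @param spec a [spectrum2d()].
#' @param window `c(lo, hi)` probe-frequency window (cm\eqn{^{-1}}).
#' @param smooth apply a light binomial smoothing to each pump-axis profile
#'   before locating the maximum (reduces the noise variance of the
#'   sub-grid peak position; negligible bias for bands much wider than the
#'   grid step).
#' @param localization `"parabola"` (five points bracketing the discrete
#'   maximum; fast, the default) or `"gauss"` (weighted log-Gaussian profile
#'   fit; more noise-robust, preferred for weak residual bands).
#' @return An object of class `"center_line"`: list with `t_w`, `points`
#'   (data frame `omega3`, `omega1_peak`, `weight`) and `window`.
#' @export
extract_center_line <- function(spec, window, smooth = TRUE,
                                localization = c("parabola", "gauss")) {
  stopifnot(inherits(spec, "spectrum2d"), length(window) == 2)
  localization <- match.arg(localization)
  a1 <- spec$omega1; a3 <- spec$omega3
  j_set <- which(a3 >= window[1] & a3 <= window[2])
  kern <- c(1, 4, 6, 4, 1) / 16
  pts <- lapply(j_set, function(j) {
    yv <- spec$amplitude[, j]
    if (smooth) {
      n <- length(yv)
      yp <- c(yv[1], yv[1], yv, yv[n], yv[n])
      yv <- as.numeric(stats::filter(yp, kern, sides = 2))[3:(n + 2)]
    }
    i <- which.max(yv)
    if (i <= 2 || i >= length(yv) - 1) return(NULL)
    pk <- if (localization == "gauss")
      .gaussfit_peak(a1, yv, i) else {
        ii <- (i - 2):(i + 2)
        .parabolic_peak(a1[ii], yv[ii])
      }
    if (is.na(pk) || pk < min(a1) || pk > max(a1)) return(NULL)
    data.frame(omega3 = a3[j], omega1_peak = pk, weight = yv[i])
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 5)
    stop("fewer than 5 usable center-line points in the window")
  structure(list(t_w = spec$t_w, points = pts, window = window),
            class = "center_line")
}

# Gaussian-profile peak localization: fits an unbaselined Gaussian to the
# points around the discrete maximum (more noise-robust than the parabola;
# the classical slice-fit localization)
.gaussfit_peak <- function(x, yv, i) {
  n <- length(yv)
  ii <- max(1, i - 6):min(n, i + 6)
  ii <- ii[yv[ii] > 0.15 * yv[i]]
  if (length(ii) < 4) {
    ii <- max(1, i - 2):min(n, i + 2)
    return(.parabolic_peak(x[ii], yv[ii]))
  }
  # linearized Gaussian fit on log amplitudes, weighted by amplitude^2
  yl <- log(yv[ii])
  w <- yv[ii]^2
  X <- cbind(1, x[ii], x[ii]^2)
  cf <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * yl)),
                 error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) {
    ii2 <- max(1, i - 2):min(n, i + 2)
    return(.parabolic_peak(x[ii2], yv[ii2]))
  }
  -cf[2] / (2 * cf[3])
}

# vertex of the least-squares parabola through (x, y)
.parabolic_peak <- function(x, y) {
  x0 <- mean(x)
  cf <- coef(lm(y ~ I(x - x0) + I((x - x0)^2)))
  if (!is.finite(cf[3]) || cf[3] >= 0) return(NA_real_)
  unname(x0 - cf[2] / (2 * cf[3]))
}

#' @export
print.center_line <- function(x, ...) {
  cat(sprintf("Center line at Tw = %.3g ps: %d points over %.1f-%.1f cm-1\n",
              x$t_w, nrow(x$points), x$window[1], x$window[2]))
  invisible(x)
}

#' Center line slope
#'
#' Weighted linear regression of the pump-axis peak positions against the
#' probe frequency.
#'
#' @param center_line a [extract_center_line()] result, or a data frame with
#'   columns `omega3`, `omega1_peak` and optionally `weight`.
#' @return Named numeric vector `c(slope, se)`.
#' @export
cls_of <- function(center_line) {
  pts <- if (inherits(center_line, "center_line")) center_line$points else center_line
  if (nrow(pts) < 5) stop("need at least 5 center-line points")
  if (sd(pts$omega3) < 1e-9) stop("degenerate omega3 spread")
  w <- if ("weight" %in% names(pts)) pts$weight else rep(1, nrow(pts))
  fit <- lm(omega1_peak ~ omega3, data = pts, weights = w)
  cf <- summary(fit)$coefficients
  c(slope = unname(cf["omega3", "Estimate"]), se = unname(cf["omega3", "Std. Error"]))
}

# default analysis window: diagonal band center +/- 0.6 x FWHM at the first
# waiting time
.auto_window <- function(series, frac = 0.6) {
  sl <- diagonal_slice(series$spectra[[1]])
  pk <- sl$wavenumber[which.max(sl$absorbance)]
  fw <- fwhm_of(sl)
  c(pk - frac * fw, pk + frac * fw)
}

#' CLS decay of a waiting-time series
#'
#' Extracts the center line and its slope for every frame and fits the
#' slopes with a single exponential plus offset,
#' \eqn{\mathrm{CLS}(T_w) = A e^{-T_w/\tau} + C} (all parameters >= 0),
#' matching the functional form of the inhomogeneous FFCF. Per-frame slope
#' standard errors propagate as weights into the decay fit.
#'
#' @param series a [tw_series()] with at least 4 waiting times.
#' @param window probe-axis window; `"auto"` (default) uses the diagonal
#'   band center +/- 0.6 FWHM of the first frame.
#' @return An object of class `"cls_decay"`: list with `t_w`, `slope`, `se`,
#'   decay parameters `amplitude`, `timescale`, `offset` (+ standard
#'   errors), the `window` used and the per-frame `center_lines`.
#' @export
cls_decay <- function(series, window = "auto") {
  stopifnot(inherits(series, "tw_series2d"))
  if (length(series$t_w) < 4) stop("need at least 4 waiting times")
  if (identical(window, "auto")) window <- .auto_window(series)
  cls <- lapply(series$spectra, function(s) {
    cl <- try(extract_center_line(s, window), silent = TRUE)
    if (inherits(cl, "try-error")) return(NULL)
    list(cl = cl, s = cls_of(cl))
  })
  ok <- !vapply(cls, is.null, TRUE)
  if (sum(ok) < 4) stop("fewer than 4 valid center-line slopes")
  slopes <- vapply(cls[ok], function(z) z$s["slope"], 0)
  ses <- vapply(cls[ok], function(z) z$s["se"], 0)
  tws <- series$t_w[ok]
  .fit_cls_decay(tws, slopes, ses, window,
                 center_lines = lapply(cls[ok], `[[`, "cl"),
                 axes = list(omega1 = series$omega1, omega3 = series$omega3))
}

.fit_cls_decay <- function(tws, slopes, ses, window = NULL,
                           center_lines = NULL, axes = NULL) {
  # guard the decay fit against unusable slopes: outside the physical range
  # or with far larger uncertainty than the rest of the series
  ok <- is.finite(slopes) & slopes > -0.05 & slopes < 1.05
  if (all(is.finite(ses)) && any(ses > 0)) {
    med <- median(ses[ok & ses > 0])
    if (is.finite(med) && med > 0) ok <- ok & ses <= 4 * med
  }
  if (sum(ok) >= 4 && !all(ok)) {
    tws <- tws[ok]; slopes <- slopes[ok]; ses <- ses[ok]
    if (!is.null(center_lines)) center_lines <- center_lines[ok]
  }
  w <- if (all(is.finite(ses)) && all(ses > 0)) 1 / ses^2 else rep(1, length(tws))
  a0 <- max(slopes[1] - min(slopes), 0.01)
  do_fit <- function(st) minpack.lm::nlsLM(
    y ~ A * exp(-t / tau) + C, data = data.frame(t = tws, y = slopes),
    start = st, weights = w,
    lower = c(0, 0.1, 0), upper = c(1.5, 1e4, 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  fit <- try(do_fit(list(A = a0, tau = diff(range(tws)) / 2,
                         C = max(min(slopes), 0))), silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- do_fit(list(A = max(a0, 0.2), tau = max(tws) / 3, C = 0.1))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(t_w = tws, slope = unname(slopes), se = unname(ses),
                 amplitude = unname(cf["A"]), timescale = unname(cf["tau"]),
                 offset = unname(cf["C"]),
                 amplitude_se = se[1], timescale_se = se[2], offset_se = se[3],
                 window = window, center_lines = center_lines, axes = axes),
            class = "cls_decay")
}

#' Build a CLS decay object from precomputed slopes
#'
#' @param t_w waiting times (ps).
#' @param slope CLS values.
#' @param se slope standard errors (optional).
#' @return A `"cls_decay"`.
#' @export
cls_decay_from_slopes <- function(t_w, slope, se = rep(NA_real_, length(t_w))) {
  stopifnot(length(t_w) == length(slope), all(diff(t_w) > 0))
  if (any(slope < -0.05 | slope > 1.05))
    warning("CLS values outside [-0.05, 1.05]")
  .fit_cls_decay(t_w, slope, se)
}

#' @export
print.cls_decay <- function(x, ...) {
  cat(sprintf("CLS decay over %d waiting times (%.3g-%.3g ps)\n",
              length(x$t_w), min(x$t_w), max(x$t_w)))
  cat(sprintf("  fit: %.3f * exp(-Tw/%.3g ps) + %.3f\n",
              x$amplitude, x$timescale, x$offset))
  invisible(x)
}

#' @export
plot.cls_decay <- function(x, ..., xlab = "Tw / ps", ylab = "CLS") {
  plot(x$t_w, x$slope, xlab = xlab, ylab = ylab,
       ylim = range(0, x$slope), ...)
  tt <- seq(min(x$t_w), max(x$t_w), length.out = 200)
  lines(tt, x$amplitude * exp(-tt / x$timescale) + x$offset, col = 2)
  invisible(x)
}

#' Determine the full Kubo FFCF from a CLS decay and a linear spectrum
#'
#' Co-fit of the CLS decay with the linear lineshape. The decay supplies the
#' inhomogeneous timescale (\eqn{\tau_1} = fitted decay timescale) and the
#' partition \eqn{\Delta_1^2 : \Delta_s^2} (amplitude : offset). The split
#' between homogeneous and inhomogeneous broadening is then set by two
#' constraints: the total linear bandwidth, and (default method `"cls0"`)
#' the initial CLS level, which falls below 1 in proportion to the
#' homogeneous contribution. The initial-CLS constraint is evaluated
#' self-consistently: for each trial homogeneous width the package's own 2D
#' simulator predicts the short-waiting-time CLS, and \eqn{\Gamma^*} is the
#' root at which it matches the observed level. Method `"shape"` instead
#' determines the split from the lineshape alone (Lorentzian vs Gaussian
#' character), which is more sensitive to wing distortions.
#'
#' @param decay a [cls_decay()] result.
#' @param linear the corresponding [linear_spectrum()] (single band).
#' @param t1_lifetime vibrational lifetime to record in the result (ps).
#' @param method `"cls0"` (default) or `"shape"`.
#' @param max_width_error maximum tolerated relative FWHM mismatch between
#'   the best-fit synthetic lineshape and the observed band (default 0.05).
#' @param bias_correct for method `"cls0"`: refine \eqn{\tau_1} and the
#'   \eqn{\Delta_1^2 : \Delta_s^2} partition by indirect inference --- the
#'   candidate FFCF is simulated, pushed through the same CLS analysis, and
#'   the parameters adjusted until the re-analyzed decay matches the
#'   observed one. This removes the systematic bias of the
#'   exponential-plus-offset decay fit over a finite waiting-time range.
#' @param n_bias_iter refinement iterations (default 2).
#' @return An [ffcf_params()] with attribute `fwhm_error` (and `fit_rss` for
#'   method `"shape"`).
#' @export
fit_ffcf <- function(decay, linear, t1_lifetime = Inf,
                     method = c("cls0", "shape"), max_width_error = 0.05,
                     bias_correct = TRUE, n_bias_iter = 2) {
  stopifnot(inherits(decay, "cls_decay"), inherits(linear, "linear_spectrum"))
  method <- match.arg(method)
  A <- decay$amplitude; C <- decay$offset; tau1 <- decay$timescale
  tot <- A + C
  frac1 <- if (tot > 1e-9) A / tot else 0
  x <- linear$wavenumber
  yn <- linear$absorbance / max(linear$absorbance)
  nu0 <- x[which.max(yn)]
  fw <- fwhm_of(linear)
  t_ref <- min(decay$t_w)
  cls0_obs <- A * exp(-t_ref / tau1) + C
  if (method == "cls0" && cls0_obs >= 0.02) {
    gh <- tryCatch(
      .solve_gamma_cls0(cls0_obs, frac1, tau1, fw, nu0, t_ref),
      error = function(e) NA_real_)
    if (!is.na(gh)) {
      if (bias_correct && frac1 > 0.02 && frac1 < 0.98) {
        for (it in seq_len(n_bias_iter)) {
          dtot <- .gauss_part(fw, gh) / (2 * sqrt(2 * log(2)))
          sim_sl <- .simulated_cls_slopes(gh, dtot, frac1, tau1, nu0, fw,
                                          decay$t_w, axes = decay$axes,
                                          window = decay$window)
          if (is.null(sim_sl)) break
          # distortion of the analysis chain relative to the ideal
          # normalized-FFCF decay for the current parameters; dividing the
          # observed slopes by it removes the shared systematic
          kwak <- frac1 * exp(-decay$t_w / tau1) + (1 - frac1)
          ideal <- sim_sl[1] * kwak / kwak[1]
          rho <- sim_sl / ideal
          corr <- decay$slope / rho
          refit <- try(.fit_cls_decay(decay$t_w, corr, decay$se),
                       silent = TRUE)
          if (inherits(refit, "try-error")) break
          tot2 <- refit$amplitude + refit$offset
          if (tot2 <= 1e-6 || refit$amplitude <= 1e-6) break
          tau_new <- refit$timescale
          frac_new <- min(max(refit$amplitude / tot2, 0.02), 0.98)
          conv <- abs(tau_new - tau1) < 0.02 * tau1 &&
            abs(frac_new - frac1) < 0.005
          tau1 <- tau_new; frac1 <- frac_new
          if (conv) break
        }
        gh2 <- tryCatch(
          .solve_gamma_cls0(cls0_obs, frac1, tau1, fw, nu0, t_ref),
          error = function(e) NA_real_)
        if (!is.na(gh2)) gh <- gh2
      }
      dtot <- .gauss_part(fw, gh) / (2 * sqrt(2 * log(2)))
      return(.ffcf_result(gh, dtot, frac1, tau1, t1_lifetime, fw,
                          max_width_error))
    }
    # fall through to the shape method when no root exists
  }
  if (method == "cls0" && cls0_obs < 0.02) {
    # essentially no inhomogeneous correlation: fully homogeneous band
    return(.ffcf_result(fw, 0, 0, tau1, t1_lifetime, fw, max_width_error))
  }
  obj <- function(th) {
    m <- .kubo_shape(th[1], th[2], frac1, tau1, nu0, x)
    sum((m - yn)^2)
  }
  init <- c(max(0.3, 0.3 * fw), max(0.6 * fw / 2.3548, 0.05))
  op <- optim(init, obj, method = "L-BFGS-B",
              lower = c(0.05, 1e-3), upper = c(2 * fw, fw))
  out <- .ffcf_result(op$par[1], op$par[2], frac1, tau1, t1_lifetime, fw,
                      max_width_error)
  attr(out, "fit_rss") <- op$value
  out
}

# simulate a single-band series from candidate Kubo parameters and push it
# through the same CLS slope analysis
.simulated_cls_slopes <- function(gh, dtot, frac1, tau1, nu0, fw, t_w,
                                  axes = NULL, window = NULL) {
  p <- try(suppressWarnings(
    ffcf_params(gh, dtot * sqrt(frac1), if (frac1 > 0) tau1 else NA_real_,
                dtot * sqrt(1 - frac1))), silent = TRUE)
  if (inherits(p, "try-error")) return(NULL)
  if (is.null(axes))
    axes <- list(omega1 = seq(nu0 - 35, nu0 + 35, length.out = 64),
                 omega3 = seq(nu0 - 35, nu0 + 35, length.out = 64))
  mdl <- mixture_model(list(spectral_component(nu0, p)),
                       omega1 = axes$omega1, omega3 = axes$omega3,
                       noise_sd = 0)
  win <- if (is.null(window)) nu0 + c(-0.6, 0.6) * fw else window
  sl <- try(vapply(t_w, function(tw)
    unname(cls_of(extract_center_line(simulate_2d(mdl, tw), win))["slope"]),
    0), silent = TRUE)
  if (inherits(sl, "try-error") || any(sl <= 0)) return(NULL)
  sl
}

# Gaussian FWHM that combines with Lorentzian gh to the observed Voigt width
# (inverse of the Olivero-Longbothum approximation)
.gauss_part <- function(fw, gh) {
  v <- (fw - 0.5346 * gh)^2 - 0.2166 * gh^2
  if (v <= 0) stop("homogeneous width exceeds the observed bandwidth")
  sqrt(v)
}

# root-solve the homogeneous FWHM so the simulated short-Tw CLS matches the
# observed level, holding the total linear width fixed
.solve_gamma_cls0 <- function(cls0_obs, frac1, tau1, fw, nu0, t_ref) {
  cls0_model <- function(gh) {
    dtot <- .gauss_part(fw, gh) / (2 * sqrt(2 * log(2)))
    p <- suppressWarnings(ffcf_params(gh, dtot * sqrt(frac1),
                                      if (frac1 > 0) tau1 else NA_real_,
                                      dtot * sqrt(1 - frac1)))
    cmp <- spectral_component(nu0, p)
    mdl <- mixture_model(list(cmp),
                         omega1 = seq(nu0 - 35, nu0 + 35, length.out = 64),
                         omega3 = seq(nu0 - 35, nu0 + 35, length.out = 64),
                         noise_sd = 0)
    S <- simulate_2d(mdl, t_ref)
    cl <- extract_center_line(S, nu0 + c(-0.6, 0.6) * fw)
    unname(cls_of(cl)["slope"])
  }
  lo <- 0.03 * fw; hi <- 0.9 * fw
  f_lo <- cls0_model(lo) - cls0_obs
  if (f_lo < 0) return(lo)  # observed CLS above the model maximum: minimal gamma
  f_hi <- tryCatch(cls0_model(hi) - cls0_obs, error = function(e) NA)
  while (is.na(f_hi) || f_hi > 0) {
    hi <- 0.8 * hi
    if (hi <= lo * 1.05) stop("no homogeneous width matches the initial CLS")
    f_hi <- tryCatch(cls0_model(hi) - cls0_obs, error = function(e) NA)
  }
  uniroot(function(g) cls0_model(g) - cls0_obs, c(lo, hi), tol = 5e-3)$root
}

.ffcf_result <- function(gh, dtot, frac1, tau1, t1_lifetime, fw,
                         max_width_error) {
  d1 <- dtot * sqrt(frac1); ds <- dtot * sqrt(1 - frac1)
  gw <- 2 * sqrt(2 * log(2)) * dtot
  fw_model <- if (gw > 0) voigt_fwhm(gw, gh) else gh
  fwhm_err <- abs(fw_model - fw) / fw
  if (fwhm_err > max_width_error)
    stop(sprintf(paste0("no (gamma_h, scale) pair reproduces the linear width: ",
                        "best model FWHM %.2f vs observed %.2f cm-1"),
                 fw_model, fw))
  out <- suppressWarnings(
    ffcf_params(gh, d1, if (d1 > 0) tau1 else NA_real_, ds,
                t1_lifetime = t1_lifetime))
  attr(out, "fwhm_error") <- fwhm_err
  out
}

# peak-normalized Kubo lineshape used inside the fit_ffcf objective
.kubo_shape <- function(gamma_h, dtot, frac1, tau1, nu0, axis) {
  d1 <- dtot * sqrt(frac1); ds <- dtot * sqrt(1 - frac1)
  p <- list(gamma_h = gamma_h, delta_1 = d1,
            tau_1 = if (d1 > 0) tau1 else NA_real_, delta_s = ds,
            t1_lifetime = Inf)
  class(p) <- "ffcf_params"
  yv <- .kubo_lineshape_ft(p, nu0, axis)
  yv / max(yv)
}
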