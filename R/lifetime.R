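# Vibrational lifetime analysis: single traces, frequency-resolved fits and
# the global two-component fit.

#' Single-exponential lifetime fit
#'
#' Weighted least-squares fit of `a * exp(-t / T1)` to a decay trace. The
#' initial estimate comes from a log-linear regression; the reported
#' uncertainty is the asymptotic standard error from the fit covariance.
#'
#' @param trace a data frame with columns `t` (ps) and `amplitude`, as
#'   returned by [simulate_pump_probe()], or a numeric time vector when `y`
#'   is given.
#' @param y amplitudes when `trace` is a time vector.
#' @param weights optional fit weights (default uniform).
#' @return An object of class `"exp_fit"`: list with `t1`, `t1_se`,
#'   `amplitude`, `rss` and the underlying `nls` fit.
#' @export
fit_single_exponential <- function(trace, y = NULL, weights = NULL) {
  if (is.data.frame(trace)) {
    t <- trace$t; yv <- trace$amplitude
  } else {
    t <- trace; yv <- y
  }
  stopifnot(is.numeric(t), is.numeric(yv), length(t) == length(yv))
  if (length(t) < 5) stop("need at least 5 time points")
  pos <- yv > 0
  if (sum(pos) >= 3) {
    sl <- unname(coef(lm(log(yv[pos]) ~ t[pos]))[2])
  } else sl <- NA
  if (is.na(sl) || sl >= 0) stop("trace does not decay")
  if (is.null(weights)) weights <- rep(1, length(t))
  fit <- minpack.lm::nlsLM(yv ~ a * exp(-t / T1),
                           start = list(a = max(yv), T1 = -1 / sl),
                           weights = weights,
                           lower = c(0, 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  structure(list(t1 = unname(cf["T1"]), t1_se = unname(se[2]),
                 amplitude = unname(cf["a"]), rss = sum(resid(fit)^2),
                 fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("T1 = %.3g +/- %.2g ps (amplitude %.3g)\n", x$t1, x$t1_se,
              x$amplitude))
  invisible(x)
}

#' Frequency-resolved vibrational lifetimes across the diagonal
#'
#' Fits an independent single-exponential decay of the diagonal-slice
#' amplitude versus waiting time at each probe frequency in the window. A
#' mixture of bands with distinct lifetimes yields frequency-dependent
#' apparent lifetimes; pure dipole differences do not (amplitude scaling
#' does not affect decay rates).
#'
#' @param series a [tw_series()] with at least 5 waiting times.
#' @param window `c(lo, hi)` probe-frequency window (cm\eqn{^{-1}}).
#' @return Data frame with columns `omega3`, `t1`, `t1_se` and `ok` (FALSE
#'   where the per-frequency fit failed).
#' @export
frequency_resolved_lifetimes <- function(series, window) {
  stopifnot(inherits(series, "tw_series2d"))
  if (length(series$t_w) < 5) stop("need at least 5 waiting times")
  slices <- lapply(series$spectra, diagonal_slice)
  nu <- slices[[1]]$wavenumber
  k <- which(nu >= window[1] & nu <= window[2])
  out <- do.call(rbind, lapply(k, function(j) {
    amp <- vapply(slices, function(s) s$absorbance[j], 0)
    f <- try(fit_single_exponential(series$t_w, amp), silent = TRUE)
    if (inherits(f, "try-error"))
      data.frame(omega3 = nu[j], t1 = NA_real_, t1_se = NA_real_, ok = FALSE)
    else
      data.frame(omega3 = nu[j], t1 = f$t1, t1_se = f$t1_se, ok = TRUE)
  }))
  rownames(out) <- NULL
  out
}

#' Global two-component lifetime fit
#'
#' Fits the waiting-time-dependent 2D band trace
#' \deqn{S(\omega, T_w) = \sum_i a_i G_i(\omega) e^{-T_w/T_{1,i}}}
#' with component shapes \eqn{G_i} frozen from a band fit of the shortest
#' waiting time and the two lifetimes shared across all frequencies. For
#' each trial lifetime pair the amplitudes are solved by non-negative linear
#' least squares; the lifetimes are optimized by bounded quasi-Newton search.
#' By default the trace is the pump-axis projection of the fundamental
#' region, whose component shapes are waiting-time independent (see
#' [diagonal_projection()]); the diagonal slice is available for comparison.
#'
#' @param series a [tw_series()] with at least 5 waiting times.
#' @param band_model a two-component `"band_fit"` supplying the frozen
#'   shapes (centers and widths).
#' @param trace `"projection"` (default) or `"slice"`.
#' @param cut probe-axis cut for the projection (see [diagonal_projection()]).
#' @param basis optional two-column matrix of component shapes evaluated on
#'   the trace's frequency grid (e.g. synthesized Kubo lineshapes),
#'   overriding the Gaussian shapes implied by `band_model`.
#' @return An object of class `"lifetime_fit"`: list with `t1` (length 2,
#'   ordered low- then high-frequency band), `t1_se`, `amplitudes`, `rss`,
#'   and the trace matrix used.
#' @export
global_lifetime_fit <- function(series, band_model,
                                trace = c("projection", "slice"), cut = NULL,
                                basis = NULL) {
  stopifnot(inherits(series, "tw_series2d"), inherits(band_model, "band_fit"))
  trace <- match.arg(trace)
  if (length(series$t_w) < 5) stop("need at least 5 waiting times")
  cmp <- band_model$components
  if (nrow(cmp) != 2) stop("'band_model' must have exactly 2 components")
  if (abs(diff(cmp$center)) < mean(cmp$fwhm) / 2)
    stop("band centers closer than half the mean width: fit is ill-conditioned")
  tr <- lapply(series$spectra, function(s)
    if (trace == "projection") diagonal_projection(s, cut = cut)
    else diagonal_slice(s))
  nu <- tr[[1]]$wavenumber
  Y <- vapply(tr, `[[`, numeric(length(nu)), "absorbance")
  if (is.null(basis)) {
    G1 <- .gauss(nu, cmp$center[1], cmp$fwhm[1])
    G2 <- .gauss(nu, cmp$center[2], cmp$fwhm[2])
  } else {
    stopifnot(is.matrix(basis), nrow(basis) == length(nu), ncol(basis) == 2)
    G1 <- basis[, 1]; G2 <- basis[, 2]
  }
  tws <- series$t_w
  yvec <- as.vector(Y)
  obj <- function(th) {
    M <- cbind(as.vector(G1 %o% exp(-tws / th[1])),
               as.vector(G2 %o% exp(-tws / th[2])))
    a <- pracma::lsqnonneg(M, yvec)$x
    sum((yvec - M %*% a)^2)
  }
  op <- optim(c(10, 20), obj, method = "L-BFGS-B", lower = c(1, 1),
              upper = c(200, 200), hessian = TRUE)
  th <- op$par
  M <- cbind(as.vector(G1 %o% exp(-tws / th[1])),
             as.vector(G2 %o% exp(-tws / th[2])))
  a <- pracma::lsqnonneg(M, yvec)$x
  # asymptotic standard errors for the lifetimes from the profile hessian
  sigma2 <- op$value / (length(yvec) - 4)
  se <- tryCatch(sqrt(2 * sigma2 * diag(solve(op$hessian))),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(t1 = th, t1_se = se, amplitudes = a, rss = op$value,
                 centers = cmp$center, trace = trace, t_w = tws),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Global two-component lifetime fit (%s trace)\n", x$trace))
  for (i in 1:2)
    cat(sprintf("  band at %.1f cm-1: T1 = %.3g +/- %.2g ps\n",
                x$centers[i], x$t1[i], x$t1_se[i]))
  invisible(x)
}

#' @export
coef.lifetime_fit <- function(object, ...) {
  setNames(object$t1, paste0("T1_", signif(object$centers, 6)))
}
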