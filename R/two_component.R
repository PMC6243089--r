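# Two-component CLS decomposition: extract the CLS decay and FFCF of an
# unknown conformational state when the other state's FFCF is known.

#' Fractional contribution of the known component along the probe axis
#'
#' Computes
#' \deqn{f_A(\omega_3, T_w) = \frac{w_A G_A(\omega_3) e^{-T_w/T_{1A}}}
#'  {w_A G_A(\omega_3) e^{-T_w/T_{1A}} + w_B G_B(\omega_3) e^{-T_w/T_{1B}}}}
#' with 2D band weights \eqn{w_i \propto} population x dipole^4 (or any
#' amplitudes proportional to them, e.g. fitted Tw -> 0 projection areas).
#'
#' @param centers length-2 centers `c(A, B)` (cm\eqn{^{-1}}).
#' @param fwhms length-2 band FWHMs.
#' @param weights length-2 2D amplitude weights at Tw = 0.
#' @param lifetimes length-2 vibrational lifetimes (ps).
#' @param t_w waiting time (ps).
#' @param omega3 probe frequencies.
#' @return Data frame with columns `omega3` and `f_A`; rows where both bands
#'   are negligible (< 1e-10 of the peak weight) are dropped.
#' @export
component_fractions <- function(centers, fwhms, weights, lifetimes, t_w,
                                omega3) {
  stopifnot(length(centers) == 2, length(fwhms) == 2, length(weights) == 2,
            length(lifetimes) == 2)
  gA <- weights[1] * .gauss(omega3, centers[1], fwhms[1]) * exp(-t_w / lifetimes[1])
  gB <- weights[2] * .gauss(omega3, centers[2], fwhms[2]) * exp(-t_w / lifetimes[2])
  den <- gA + gB
  keep <- den > 1e-10 * max(den)
  data.frame(omega3 = omega3[keep], f_A = gA[keep] / den[keep])
}

#' Decompose a mixed center line into known and unknown components
#'
#' Pointwise solves
#' \eqn{\mathrm{mixed}(\omega_3) = f_A A(\omega_3) + (1-f_A) B(\omega_3)}
#' for the unknown component's center line \eqn{B}. Points with
#' \eqn{1 - f_A < 0.1} are dropped: the inversion amplifies errors by
#' \eqn{1/(1-f_A)}, and the cutoff bounds the amplification at 10x.
#'
#' @param mixed `"center_line"` of the two-component spectrum.
#' @param known_A `"center_line"` of the known component (interpolated onto
#'   the mixed line's probe frequencies).
#' @param fractions data frame from [component_fractions()] at the same
#'   waiting time.
#' @param min_unknown_fraction drop threshold on `1 - f_A` (default 0.1).
#' @return A `"center_line"` for the unknown component (weights copied from
#'   the mixed line).
#' @export
decompose_center_line <- function(mixed, known_A, fractions,
                                  min_unknown_fraction = 0.1) {
  stopifnot(inherits(mixed, "center_line"), inherits(known_A, "center_line"))
  o3 <- mixed$points$omega3
  A <- approx(known_A$points$omega3, known_A$points$omega1_peak, xout = o3)$y
  fA <- approx(fractions$omega3, fractions$f_A, xout = o3)$y
  keep <- !is.na(A) & !is.na(fA) & (1 - fA) >= min_unknown_fraction
  if (sum(keep) < 5)
    stop("fewer than 5 center-line points survive the decomposition guard")
  B <- (mixed$points$omega1_peak[keep] - fA[keep] * A[keep]) / (1 - fA[keep])
  structure(list(t_w = mixed$t_w,
                 points = data.frame(omega3 = o3[keep], omega1_peak = B,
                                     weight = mixed$points$weight[keep]),
                 window = mixed$window),
            class = "center_line")
}

# shift-and-stretch transform of a 2D band: value at (w1, w3) is taken from
# (c + (w1 - c - d)/k, c + (w3 - c - d)/k); d translates the band along the
# diagonal, k stretches it isotropically about its center
.shift_stretch_2d <- function(S, ax1, ax3, center, d, k, cols = NULL) {
  sp <- spectrum2d(ax1, ax3, 0, S)
  if (is.null(cols)) cols <- seq_along(ax3)
  x1 <- center + (ax1 - center - d) / k
  out <- matrix(0, length(ax1), length(cols))
  x1c <- pmin(pmax(x1, min(ax1)), max(ax1))
  inside1 <- x1 >= min(ax1) & x1 <= max(ax1)
  for (jj in seq_along(cols)) {
    x3 <- center + (ax3[cols[jj]] - center - d) / k
    if (x3 < min(ax3) || x3 > max(ax3)) next
    v <- .interp2(sp, x1c, rep(x3, length(ax1)))
    v[!inside1] <- 0
    out[, jj] <- v
  }
  out
}

# Calibrate the known component's 2D model against the measured series in a
# probe-frequency region where the known band dominates: a global diagonal
# shift d and width factor k, plus one amplitude scale per waiting time.
# 'low2d' optionally supplies per-frame unknown-band model matrices that are
# amplitude-fitted jointly and subtracted.
.calibrate_known <- function(series, unit_frames, center, fwhm, low2d = NULL,
                             k_grid = c(0.92, 0.96, 1, 1.04, 1.08),
                             d_bound = 2, reg_lo = NULL) {
  a3 <- series$omega3
  if (is.null(reg_lo)) reg_lo <- center + 0.3 * fwhm
  reg <- which(a3 >= reg_lo & a3 <= center + 1.6 * fwhm)
  if (length(reg) < 4) reg <- utils::tail(which(a3 >= center), 6)
  nfr <- length(series$spectra)
  eval_dk <- function(d, k) {
    tot <- 0
    scales <- numeric(nfr)
    for (i in seq_len(nfr)) {
      Ks <- .shift_stretch_2d(unit_frames[[i]], series$omega1, a3, center,
                              d, k, cols = reg)
      Dm <- series$spectra[[i]]$amplitude[, reg, drop = FALSE]
      if (is.null(low2d)) {
        s <- sum(Dm * Ks) / sum(Ks * Ks)
        scales[i] <- max(s, 0)
        tot <- tot + sum((Dm - scales[i] * Ks)^2)
      } else {
        L <- low2d[[i]][, reg, drop = FALSE]
        M <- cbind(as.vector(Ks), as.vector(L))
        cf <- tryCatch(qr.solve(M, as.vector(Dm)), error = function(e) c(0, 0))
        scales[i] <- max(cf[1], 0)
        tot <- tot + sum((as.vector(Dm) - M %*% pmax(cf, 0))^2)
      }
    }
    list(rss = tot, scales = scales)
  }
  best_d <- function(k)
    optimize(function(d) eval_dk(d, k)$rss, c(-d_bound, d_bound), tol = 1e-3)
  if (is.null(low2d) || length(k_grid) == 1) {
    # flank-only first pass cannot separate a stretch from an amplitude
    # rescale; width factor held fixed
    k <- k_grid[1]
    if (is.null(low2d)) k <- 1
    d <- best_d(k)$minimum
  } else {
    scan <- lapply(k_grid, best_d)
    rss_k <- vapply(scan, `[[`, 0, "objective")
    i0 <- which.min(rss_k)
    k <- k_grid[i0]
    # parabolic refinement of k on the scanned profile
    if (i0 > 1 && i0 < length(k_grid)) {
      kk <- k_grid[(i0 - 1):(i0 + 1)]; rr <- rss_k[(i0 - 1):(i0 + 1)]
      den <- (rr[1] - 2 * rr[2] + rr[3])
      if (is.finite(den) && den > 0)
        k <- kk[2] - 0.5 * (kk[3] - kk[1]) / 2 * (rr[3] - rr[1]) / den
      k <- min(max(k, min(k_grid)), max(k_grid))
    }
    d <- best_d(k)$minimum
  }
  res <- eval_dk(d, k)
  list(d = d, k = k, scales = res$scales, rss = res$rss, region = reg)
}

# Peak-consistent decomposition of one frame: at the measured mixed peak
# x*(omega3), stationarity of S_known + (Gaussian unknown profile) gives the
# unknown center exactly:
#   B = x* - S_known'(x*) * w_B^2 / (8 ln 2 * [S_mix(x*) - S_known(x*)])
# The unknown's pump-axis profile width w_B is estimated per frame from the
# width of the residual profile S_mix - S_known at probe frequencies where
# the unknown dominates.
.decompose_frame_peak <- function(spec_mix, known_amp, window,
                                  min_unknown_fraction = 0.1,
                                  wb = NULL) {
  a1 <- spec_mix$omega1; a3 <- spec_mix$omega3
  cl <- extract_center_line(spec_mix, window)
  o3 <- cl$points$omega3; xstar <- cl$points$omega1_peak
  j_of <- match(round(o3, 9), round(a3, 9))
  Sh_v <- dSh_v <- exc <- wres <- numeric(length(o3))
  for (q in seq_along(o3)) {
    j <- j_of[q]
    sf <- splinefun(a1, known_amp[, j])
    mf <- splinefun(a1, spec_mix$amplitude[, j])
    Sh_v[q] <- sf(xstar[q])
    dSh_v[q] <- sf(xstar[q], deriv = 1)
    exc[q] <- mf(xstar[q]) - Sh_v[q]
    r <- spec_mix$amplitude[, j] - known_amp[, j]
    wres[q] <- tryCatch(fwhm_of(a1, r), error = function(e) NA_real_)
  }
  fA <- Sh_v / (Sh_v + exc)
  if (is.null(wb)) {
    wb <- median(wres[fA < 0.3], na.rm = TRUE)
    if (!is.finite(wb)) wb <- median(wres, na.rm = TRUE)
  }
  keep <- (1 - fA) >= min_unknown_fraction & exc > 0
  if (sum(keep) < 5)
    stop("fewer than 5 center-line points survive the decomposition guard")
  B <- xstar - dSh_v * wb^2 / (8 * log(2) * exc)
  list(cl = structure(list(t_w = spec_mix$t_w,
                           points = data.frame(omega3 = o3[keep],
                                               omega1_peak = B[keep],
                                               weight = cl$points$weight[keep]),
                           window = window),
                      class = "center_line"),
       f_A = fA, wb = wb)
}

#' Extract the CLS decay of the unknown component of a two-band series
#'
#' Implements the fixed-component analysis: the known component's 2D band is
#' forward-simulated (noiseless) from its FFCF at every waiting time on the
#' series axes, calibrated against the measured spectra in the
#' probe-frequency region where it dominates (one global center shift and
#' width factor, one amplitude scale per waiting time), and removed from the
#' measured center line in the unknown band's window; the slopes of the
#' resulting unknown-component center line give its CLS decay.
#'
#' Three removal schemes are available. `method = "residual"` (default)
#' subtracts the calibrated known-component spectrum and extracts the center
#' line of the residual band directly. `method = "peak"` solves the
#' peak-stationarity condition of the mixed pump-axis profile at each probe
#' frequency, which is exact when the unknown's profile is locally Gaussian.
#' `method = "linear"` is the classical amplitude-fraction convex
#' combination via [component_fractions()] and [decompose_center_line()].
#'
#' With `passes = 2` (default) the extraction runs twice: the first pass's
#' unknown-band FFCF estimate is simulated and included in the second
#' calibration, removing the unknown band's tail from the calibration
#' region.
#'
#' @param series the measured two-component [tw_series()].
#' @param known_model a [spectral_component()] holding the known component's
#'   center and FFCF (population/dipole are ignored; amplitudes are
#'   calibrated against the data).
#' @param mixture_fit list with elements `linear_fit` (two-component
#'   `"band_fit"`, components ordered low/high) and `lifetimes` (a
#'   `"lifetime_fit"` or length-2 numeric, same order). Band shapes locate
#'   the unknown window and seed the `"linear"` method's fractions.
#' @param window probe window for the unknown band; `"auto"` uses the
#'   unknown band center +/- 0.6 of its fitted width.
#' @param method `"residual"`, `"peak"` or `"linear"`.
#' @param passes number of calibration passes (1-4; later passes co-fit a
#'   model of the unknown band refined from the previous extraction).
#' @param calibrate_width also calibrate the known band's width factor in
#'   the second pass (within 8%); disable to hold the supplied width.
#' @param anharmonicity passed to the known-component simulation.
#' @return A `"cls_decay"` for the unknown component, with attribute
#'   `calibration` (list: center shift `d`, width factor `k`, per-frame
#'   `scales`).
#' @export
extract_component_cls <- function(series, known_model, mixture_fit,
                                  window = "auto",
                                  method = c("residual", "peak", "linear"),
                                  passes = 2, anharmonicity = 25,
                                  calibrate_width = TRUE) {
  replicates <- NULL
  if (is.list(series) && !inherits(series, "tw_series2d")) {
    replicates <- series
    series <- average_series(series)
  }
  stopifnot(inherits(series, "tw_series2d"),
            inherits(known_model, "spectral_component"))
  method <- match.arg(method)
  bf <- mixture_fit$linear_fit
  if (is.null(bf)) bf <- mixture_fit$projection_fit
  stopifnot(inherits(bf, "band_fit"), nrow(bf$components) == 2)
  lt <- mixture_fit$lifetimes
  if (inherits(lt, "lifetime_fit")) lt <- lt$t1
  cmp <- bf$components
  i_known <- which.min(abs(cmp$center - known_model$nu_0))
  i_unk <- 3 - i_known
  tws <- series$t_w
  if (identical(window, "auto")) {
    window <- cmp$center[i_unk] + c(-0.6, 0.6) * cmp$fwhm[i_unk]
    # keep the window on the unknown side of the two bands
    mid <- mean(cmp$center)
    if (cmp$center[i_unk] < cmp$center[i_known])
      window[2] <- min(window[2], mid) else window[1] <- max(window[1], mid)
  }
  # unit-amplitude known-component frames (noiseless, no lifetime decay:
  # amplitudes are calibrated per frame)
  fK <- known_model$ffcf
  unitK <- spectral_component(known_model$nu_0,
                              suppressWarnings(
                                ffcf_params(fK$gamma_h, fK$delta_1, fK$tau_1,
                                            fK$delta_s, t1_lifetime = Inf)))
  modelK <- mixture_model(list(unitK), omega1 = series$omega1,
                          omega3 = series$omega3, noise_sd = 0,
                          anharmonicity = anharmonicity)
  unit_frames <- lapply(tws, function(tw) .sim_noiseless_2d(modelK, tw))
  low2d <- NULL
  out <- NULL
  for (pass in seq_len(max(1, min(4, passes)))) {
    cal <- .calibrate_known(series, unit_frames, known_model$nu_0,
                            cmp$fwhm[i_known], low2d = low2d,
                            k_grid = if (calibrate_width)
                              c(0.92, 0.96, 1, 1.04, 1.08) else 1,
                            reg_lo = if (is.null(low2d)) NULL else
                              mean(cmp$center))
    slopes <- ses <- numeric(length(tws))
    cls_list <- vector("list", length(tws))
    for (i in seq_along(tws)) {
      SK <- cal$scales[i] *
        .shift_stretch_2d(unit_frames[[i]], series$omega1, series$omega3,
                          known_model$nu_0, cal$d, cal$k)
      if (method == "residual") {
        R <- series$spectra[[i]]$amplitude - SK
        cl <- extract_center_line(
          spectrum2d(series$omega1, series$omega3, tws[i], R), window,
          localization = "gauss")
        if (!is.null(replicates)) {
          # per-replicate slopes: the decay point is their mean and its
          # uncertainty the between-replicate scatter (triplicate protocol)
          rep_sl <- vapply(replicates, function(sr) {
            Rr <- sr$spectra[[i]]$amplitude - SK
            out <- try(cls_of(extract_center_line(
              spectrum2d(sr$omega1, sr$omega3, tws[i], Rr), window,
              localization = "gauss")), silent = TRUE)
            if (inherits(out, "try-error")) NA_real_ else out["slope"]
          }, 0)
          rep_sl <- rep_sl[is.finite(rep_sl)]
          if (length(rep_sl) >= 2) {
            slopes[i] <- mean(rep_sl)
            ses[i] <- max(sd(rep_sl) / sqrt(length(rep_sl)), 1e-4)
            cls_list[[i]] <- cl
            next
          }
        }
      } else if (method == "peak") {
        dec <- .decompose_frame_peak(series$spectra[[i]], SK, window)
        cl <- dec$cl
      } else {
        mixed <- extract_center_line(series$spectra[[i]], window)
        knownK <- extract_center_line(
          spectrum2d(series$omega1, series$omega3, tws[i], SK),
          known_model$nu_0 + cal$d + c(-1, 1) * cmp$fwhm[i_known])
        w2d <- cmp$area
        fr <- component_fractions(
          c(known_model$nu_0 + cal$d, cmp$center[i_unk]),
          cmp$fwhm[c(i_known, i_unk)],
          w2d[c(i_known, i_unk)], lt[c(i_known, i_unk)], tws[i],
          series$omega3)
        cl <- decompose_center_line(mixed, knownK, fr)
      }
      s <- cls_of(cl)
      slopes[i] <- s["slope"]; ses[i] <- s["se"]
      cls_list[[i]] <- cl
    }
    out <- .fit_cls_decay(tws, slopes, ses, window, center_lines = cls_list,
                          axes = list(omega1 = series$omega1,
                                      omega3 = series$omega3))
    attr(out, "calibration") <- cal[c("d", "k", "scales")]
    if (pass == max(1, min(4, passes))) break
    # unknown band's width measured from the first residual frame's
    # projection (the Gaussian band fit overestimates it under overlap)
    SK1 <- cal$scales[1] *
      .shift_stretch_2d(unit_frames[[1]], series$omega1, series$omega3,
                        known_model$nu_0, cal$d, cal$k)
    R1 <- spectrum2d(series$omega1, series$omega3, tws[1],
                     series$spectra[[1]]$amplitude - SK1)
    wU <- tryCatch(fwhm_of(diagonal_projection(R1)),
                   error = function(e) cmp$fwhm[i_unk])
    # build the unknown-band model for the second calibration pass
    lowf <- try(.ffcf_from_decay_and_width(out, wU), silent = TRUE)
    if (inherits(lowf, "try-error")) break
    unitU <- spectral_component(cmp$center[i_unk],
                                suppressWarnings(
                                  ffcf_params(lowf$gamma_h, lowf$delta_1,
                                              lowf$tau_1, lowf$delta_s,
                                              t1_lifetime = Inf)))
    modelU <- mixture_model(list(unitU), omega1 = series$omega1,
                            omega3 = series$omega3, noise_sd = 0,
                            anharmonicity = anharmonicity)
    low2d <- lapply(tws, function(tw) .sim_noiseless_2d(modelU, tw))
  }
  out
}

# rough FFCF from a CLS decay plus a bandwidth: partitions the (Gaussian)
# width implied by the fitted fwhm between homogeneous and inhomogeneous
# parts using the initial CLS value; used only to model the unknown band
# inside the second calibration pass
.ffcf_from_decay_and_width <- function(decay, fwhm) {
  cls0 <- decay$amplitude + decay$offset
  cls0 <- min(max(cls0, 0.05), 0.95)
  dtot_fw <- fwhm * sqrt(cls0)
  gh <- max(fwhm * (1 - sqrt(cls0)) * 0.9, 0.2)
  dtot <- dtot_fw / (2 * sqrt(2 * log(2)))
  f1 <- if (decay$amplitude + decay$offset > 0)
    decay$amplitude / (decay$amplitude + decay$offset) else 0
  suppressWarnings(ffcf_params(gh, dtot * sqrt(f1),
                               max(decay$timescale, 1), dtot * sqrt(1 - f1)))
}

#' Compare two CLS decays
#'
#' Chi-square of pointwise differences at common waiting times against the
#' combined slope uncertainties. The decays are declared "overlapped" when
#' the reduced chi-square is below `threshold`.
#'
#' @param d1,d2 `"cls_decay"` objects with overlapping waiting-time ranges.
#' @param threshold reduced chi-square limit for the "overlapped" verdict.
#' @param min_se uncertainty floor per slope (guards against zero standard
#'   errors on noiseless synthetic data).
#' @return List with `overlapped` (logical), `chisq`, `reduced_chisq`, `df`.
#' @export
compare_cls <- function(d1, d2, threshold = 2, min_se = 0.005) {
  stopifnot(inherits(d1, "cls_decay"), inherits(d2, "cls_decay"))
  common <- intersect(d1$t_w, d2$t_w)
  if (length(common) == 0) {
    lo <- max(min(d1$t_w), min(d2$t_w)); hi <- min(max(d1$t_w), max(d2$t_w))
    if (hi <= lo) stop("waiting-time ranges do not overlap")
    common <- d1$t_w[d1$t_w >= lo & d1$t_w <= hi]
    if (length(common) == 0) stop("no common waiting times in the overlap")
  }
  i1 <- match(common, d1$t_w)
  s1 <- d1$slope[i1]; e1 <- d1$se[i1]
  if (all(common %in% d2$t_w)) {
    i2 <- match(common, d2$t_w)
    s2 <- d2$slope[i2]; e2 <- d2$se[i2]
  } else {
    s2 <- approx(d2$t_w, d2$slope, xout = common)$y
    e2 <- if (all(!is.finite(d2$se))) rep(NA_real_, length(common)) else
      approx(d2$t_w, ifelse(is.finite(d2$se), d2$se, min_se), xout = common)$y
  }
  e1[!is.finite(e1)] <- min_se; e2[!is.finite(e2)] <- min_se
  e1 <- pmax(e1, min_se); e2 <- pmax(e2, min_se)
  chisq <- sum((s1 - s2)^2 / (e1^2 + e2^2))
  df <- length(common)
  list(overlapped = (chisq / df) < threshold, chisq = chisq,
       reduced_chisq = chisq / df, df = df)
}
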