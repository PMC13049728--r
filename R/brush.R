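#' Steric polymer-brush force
#'
#' Alexander-de Gennes entropic repulsion of a grafted polymer layer
#' compressed by a sphere of radius R, in the exponential form
#' F(h) = 50 kB T R N^(3/2) L exp(-2 pi h / L), nominally valid for
#' 0.1 < h/L < 0.8. Here L is the brush (glycocalyx) length, N the
#' grafting density and h the tip-sample separation; log F is affine in h
#' with slope -2 pi / L, which is what the fitting stage exploits.
#'
#' @param L Brush length, nm.
#' @param N Grafting density, m^-2.
#' @param R Probe radius, um.
#' @param T Temperature, K. Default 309.35 K (36.2 C).
#' @param h Separation, nm (vectorised, non-negative).
#' @return Force, pN; positive and strictly decreasing in `h`.
#' @examples
#' brush_force(300, 1e14, 1.25, 309.35, 90)  # ~12.2 pN
#' @export
brush_force <- function(L, N, R = 1.25, T = 309.35, h) {
  if (L <= 0 || N <= 0 || R <= 0 || T <= 0)
    stop("L, N, R and T must all be positive")
  if (any(h < 0)) stop("separation h must be non-negative")
  brush_prefactor(L, N, R, T) * exp(-2 * pi * h / L)
}

# h -> 0 limit of the brush force, pN
brush_prefactor <- function(L, N, R, T) {
  50 * .kB * T * (R * .UM) * N^1.5 * (L * .NM) / .PN
}

# invert the prefactor for N given L (nm), P (pN)
prefactor_to_N <- function(P, L, R, T) {
  (P * .PN / (50 * .kB * T * (R * .UM) * (L * .NM)))^(2 / 3)
}

#' Weighted log-linear brush initialiser
#'
#' Weighted least-squares regression of log(force) on separation. With the
#' default weights f^2 (the delta-method variance stabiliser for the log
#' transform under additive force noise) this is the standard initialiser
#' for the brush fit: slope -2 pi / L and intercept log of the prefactor.
#'
#' @param h Separations, nm.
#' @param f Positive residual forces, pN.
#' @param weights Regression weights; default `f^2`.
#' @return Named vector `c(intercept, slope)` of the weighted fit of
#'   `log(f)` on `h`.
#' @export
brush_loglinear <- function(h, f, weights = f^2) {
  stopifnot(length(h) == length(f), all(f > 0))
  fit <- lm.wfit(cbind(1, h), log(f), w = weights)
  setNames(fit$coefficients, c("intercept", "slope"))
}

#' Fit the polymer-brush model to the long-range force residual
#'
#' Implements the brush stage of the two-regime decomposition: the fitted
#' Hertz contact force is subtracted, the remaining long-range force on the
#' non-contact side is expressed against the separation h from the
#' brush-compressed surface (the Hertz contact point), and the exponential
#' brush law is fitted. A weighted log-linear regression initialises (L, N);
#' the h-window is then iterated to the nominal validity band
#' `0.1 <= h/L <= 0.8` (at most `max_iter` passes, converged when L moves
#' by < 1%), and a Levenberg-Marquardt refinement of (L, prefactor) in
#' force space gives the final estimate.
#'
#' @param curve A baseline-corrected approach [force_curve()].
#' @param hertz A [fit_hertz()] result for the same curve (supplies the
#'   contact point and the contact force to subtract).
#' @param window Validity band as a fraction of L, default `c(0.1, 0.8)`.
#' @param max_iter Maximum window iterations, default 10.
#' @param detect_k Detection threshold: the median force over the 16
#'   non-contact points nearest the surface must exceed `detect_k` times
#'   the baseline noise RMS (default 3), and at least 8 points must rise
#'   above 2x the noise. A median over the near-contact block is robust in
#'   both directions: a true brush keeps it high even when the contact
#'   point is biased, while i.i.d. noise essentially never lifts a 16-point
#'   median past 3 RMS.
#' @return An object of class `brush_fit` with `L` (nm), `N` (m^-2),
#'   `prefactor` (pN), `h_window` (nm), `residual_rms` (pN),
#'   `r_squared_loglinear`, `n_points`, `detected`, `converged`, `flags`
#'   and the windowed data. When no brush force is detected, a minimal
#'   object with `detected = FALSE` is returned.
#' @export
fit_brush <- function(curve, hertz, window = c(0.1, 0.8), max_iter = 10,
                      detect_k = 3) {
  require_baseline(curve)
  stopifnot(inherits(hertz, "hertz_fit"))
  z <- curve$z; f <- curve$force; d <- curve$deflection
  h <- (z - hertz$z0) + d
  out <- h > 0
  resid <- f[out]
  h <- h[out]
  rms <- attr(curve, "baseline_rms")
  if (is.null(rms) || !is.finite(rms)) rms <- 0
  usable <- resid > max(2 * rms, 1e-3)
  none <- structure(list(detected = FALSE, L = NA_real_, N = NA_real_,
                         flags = "no_brush"), class = "brush_fit")
  if (sum(usable) < 8L) return(none)
  near <- head(order(h), 16L)
  if (median(resid[near]) <= max(detect_k * rms, 1e-3)) return(none)
  flags <- character()
  # initial L from an unwindowed log-linear pass over all usable points
  cf <- brush_loglinear(h[usable], resid[usable])
  if (!is.finite(cf["slope"]) || cf["slope"] >= 0) return(none)
  L <- -2 * pi / cf["slope"]
  converged <- FALSE
  sel <- usable
  for (it in seq_len(max_iter)) {
    band <- h >= window[1] * L & h <= window[2] * L
    sel <- band & usable
    if (sum(sel) < 8L) {
      flags <- c(flags, "brush_window_collapse")
      return(structure(list(detected = TRUE, L = NA_real_, N = NA_real_,
                            flags = flags, converged = FALSE),
                       class = "brush_fit"))
    }
    cf <- brush_loglinear(h[sel], resid[sel])
    L_new <- -2 * pi / cf["slope"]
    if (!is.finite(L_new) || L_new <= 0) {
      flags <- c(flags, "brush_window_collapse")
      return(structure(list(detected = TRUE, L = NA_real_, N = NA_real_,
                            flags = flags, converged = FALSE),
                       class = "brush_fit"))
    }
    if (abs(L_new - L) / L < 0.01) { L <- L_new; converged <- TRUE; break }
    L <- L_new
  }
  if (max(h[sel]) > max(h) - 1e-9 || window[2] * L > max(h))
    flags <- c(flags, "window_truncated")
  P <- exp(unname(cf["intercept"]))
  r2 <- loglinear_r2(h[sel], resid[sel], cf)
  # nonlinear refinement in force space
  dat <- data.frame(h = h[sel], r = resid[sel])
  nl <- tryCatch(
    minpack.lm::nlsLM(r ~ P * exp(-2 * pi * h / L), data = dat,
                      start = list(P = P, L = unname(L)),
                      lower = c(1e-6, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(nl)) {
    cf_nl <- coef(nl)
    P <- unname(cf_nl["P"]); L <- unname(cf_nl["L"])
    rss <- sum(residuals(nl)^2)
  } else {
    flags <- c(flags, "brush_refine_failed")
    rss <- sum((resid[sel] - P * exp(-2 * pi * h[sel] / L))^2)
  }
  N <- prefactor_to_N(P, L, curve$probe$radius, curve$temperature)
  structure(list(detected = TRUE, L = unname(L), N = N, prefactor = P,
                 h_window = range(h[sel]), residual_rms = sqrt(rss / sum(sel)),
                 r_squared_loglinear = r2, n_points = sum(sel),
                 converged = converged, flags = flags,
                 data = list(h = h[sel], resid = resid[sel])),
            class = "brush_fit")
}

loglinear_r2 <- function(h, f, cf) {
  y <- log(f)
  yhat <- cf["intercept"] + cf["slope"] * h
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' @export
print.brush_fit <- function(x, ...) {
  if (!isTRUE(x$detected)) {
    cat("Brush fit: no long-range brush force detected\n")
    return(invisible(x))
  }
  if (is.na(x$L)) {
    cat("Brush fit: detected but not fitted (", paste(x$flags, collapse = ", "),
        ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Brush fit: L = %.1f nm, N = %.3g m^-2 (prefactor %.3g pN)\n",
              x$L, x$N, x$prefactor))
  cat(sprintf("  h window [%.1f, %.1f] nm, %d points, log-linear R^2 = %.4f\n",
              x$h_window[1], x$h_window[2], x$n_points, x$r_squared_loglinear))
  invisible(x)
}

#' @export
coef.brush_fit <- function(object, ...) c(L = object$L, N = object$N)

#' Decompose a force curve into elastic and brush components
#'
#' The two-regime procedure for spherical-probe curves on glycocalyx-bearing
#' cells: (1) baseline correction, (2) contact-point scan, (3) Hertz fit
#' over the deep indentation window, where the glycocalyx is assumed almost
#' squeezed, with an additive offset absorbing the saturated brush force,
#' (4) brush fit on the long-range residual, (5) quality flags. The result
#' carries the apparent Young's modulus E and the glycocalyx length L.
#' Deterministic given the curve and configuration.
#'
#' @param curve An approach [force_curve()] (raw or baseline-corrected).
#' @param geometry A spherical [probe_geometry()]; the procedure is defined
#'   for the colloidal sphere probe only.
#' @param config Configuration list, see [decompose_config()].
#' @return An object of class `curve_decomposition`: list with `hertz`
#'   ([fit_hertz()] result or `NULL`), `brush` ([fit_brush()] result or
#'   `NULL`), `brush_detected`, `quality_flags` (subset of `"no_contact"`,
#'   `"no_brush"`, `"poor_hertz_fit"`, `"window_truncated"`,
#'   `"hertz_nonconverged"`, `"brush_window_collapse"`,
#'   `"brush_refine_failed"`) and the corrected curve.
#' @examples
#' sim <- simulate_curve(sim_config(seed = 7))
#' dec <- decompose_curve(sim$curve)
#' coef(dec)
#' @export
decompose_curve <- function(curve, geometry = curve$probe,
                            config = decompose_config()) {
  if (geometry$kind != "sphere")
    stop("the two-regime decomposition is defined for spherical probes")
  if (!isTRUE(curve$baseline_corrected))
    curve <- correct_baseline(curve, config$baseline_fraction)
  flags <- character()
  cp <- tryCatch(estimate_contact_point(curve), error = function(e) NULL)
  if (is.null(cp)) {
    return(structure(list(hertz = NULL, brush = NULL, brush_detected = FALSE,
                          quality_flags = "no_contact", curve = curve,
                          config = config),
                     class = "curve_decomposition"))
  }
  hz <- fit_hertz(curve, geometry,
                  window = hertz_window("deep", q = config$hertz_q),
                  poisson = config$poisson, z0 = cp$z0,
                  z0_bracket = max(3 * cp$uncertainty, 20),
                  offset = config$hertz_offset)
  if (!hz$converged) flags <- c(flags, "hertz_nonconverged")
  noise <- attr(curve, "baseline_rms")
  if (hz$residual_rms > max(3 * noise, 0.02 * max(curve$force)))
    flags <- c(flags, "poor_hertz_fit")
  br <- fit_brush(curve, hz, window = config$brush_window)
  detected <- isTRUE(br$detected)
  if (!detected) flags <- c(flags, "no_brush")
  flags <- unique(c(flags, br$flags[br$flags != "no_brush"]))
  if (detected && isTRUE(config$joint_refine)) {
    jr <- joint_refine(curve, hz, br, z0_center = cp$z0)
    if (is.null(jr)) {
      flags <- c(flags, "joint_refine_failed")
    } else if (jr$brush$prefactor <= max(3 * noise, 1e-3)) {
      # with the contact point now well determined, a prefactor at noise
      # level means the initial detection was an artifact of a biased z0
      detected <- FALSE
      flags <- unique(c(flags, "no_brush"))
      hz <- jr$hertz
    } else {
      hz <- jr$hertz; br <- jr$brush
      # staged-stage mishaps are superseded by a successful joint fit
      flags <- setdiff(flags, "brush_window_collapse")
      br$flags <- setdiff(br$flags, "brush_window_collapse")
      # re-window the brush diagnostics at the refined geometry
      br2 <- fit_brush(curve, hz, window = config$brush_window)
      if (isTRUE(br2$detected) && !is.na(br2$L)) {
        br$h_window <- br2$h_window
        br$r_squared_loglinear <- br2$r_squared_loglinear
        br$n_points <- br2$n_points
      }
    }
  }
  structure(list(hertz = hz, brush = if (detected) br else NULL,
                 brush_detected = detected, quality_flags = flags,
                 contact = cp, curve = curve, config = config),
            class = "curve_decomposition")
}

# Joint full-curve refinement of the two-regime model. The staged pipeline
# (contact scan -> deep-window Hertz -> windowed brush) is a good
# initialiser but leaves (z0, prefactor, offset) weakly identified on noisy
# curves because the deep window alone carries little curvature contrast;
# refitting all four parameters against the entire curve, with the brush
# term saturating at its prefactor under contact, pins z0 at the
# brush-to-contact transition and removes that bias. The (z0, L) plane is
# first scanned on a coarse grid - the two amplitudes (Hertz prefactor and
# brush prefactor) are profiled out by linear least squares at each node -
# so the Levenberg-Marquardt polish starts near the global optimum rather
# than wherever the staged fits landed. Returns NULL when the refinement
# fails; callers fall back to the staged estimates.
joint_refine <- function(curve, hz, br, z0_center = hz$z0) {
  z <- curve$z; f <- curve$force; d <- curve$deflection
  p <- hz$power
  # a long-range brush biases the contact scan toward larger z, so the grid
  # reaches much further below the scan estimate than above it
  z0_grid <- seq(z0_center - 250, z0_center + 40, by = 10)
  z0_grid <- unique(c(z0_grid[z0_grid > min(z) & z0_grid < max(z)], hz$z0))
  L_grid <- exp(seq(log(50), log(1000), length.out = 24))
  if (is.finite(br$L) && br$L > 0) L_grid <- sort(c(L_grid, br$L))
  profile_scan <- function(z0_grid, L_grid, best = NULL) {
    for (z0c in z0_grid) {
      delta <- pmax(0, (z0c - z) - d)
      h <- pmax(0, (z - z0c) + d)
      x1 <- delta^p
      s11 <- sum(x1 * x1); b1 <- sum(f * x1)
      for (L in L_grid) {
        x2 <- exp(-2 * pi * h / L)
        s12 <- sum(x1 * x2); s22 <- sum(x2 * x2); b2 <- sum(f * x2)
        det <- s11 * s22 - s12^2
        if (!is.finite(det) || det <= 1e-12 * s11 * s22) next
        C <- (b1 * s22 - b2 * s12) / det
        P <- (s11 * b2 - s12 * b1) / det
        if (!is.finite(C) || !is.finite(P) || C <= 0 || P <= 0) next
        sse <- sum((f - C * x1 - P * x2)^2)
        if (is.null(best) || sse < best$sse)
          best <- list(z0 = z0c, L = L, C = C, P = P, sse = sse)
      }
    }
    best
  }
  best <- profile_scan(z0_grid, L_grid)
  if (is.null(best)) return(NULL)
  # multi-resolution refinement of the profiled scan: the residual surface
  # is a long shallow valley in (z0, L) when the brush is long relative to
  # the contact signal, where a derivative-based polish alone stalls
  for (span in list(c(8, 1.25), c(1.6, 1.06), c(0.32, 1.015))) {
    best <- profile_scan(seq(best$z0 - span[1], best$z0 + span[1],
                             length.out = 9),
                         best$L * seq(1 / span[2], span[2], length.out = 9),
                         best)
  }
  # polish; the far tail (h >> L) carries no signal and a positive-only
  # model would chase its noise, so it is dropped
  keep <- (z - best$z0) + d < 1.5 * best$L
  if (sum(keep) < 16L) keep <- rep(TRUE, length(z))
  zk <- z[keep]; fk <- f[keep]; dk <- d[keep]
  dat <- data.frame(z = zk, f = fk, d = dk)
  fitfun <- function(z0, C, P, L) {
    delta <- pmax(0, (z0 - zk) - dk)
    h <- pmax(0, (zk - z0) + dk)
    C * delta^p + P * exp(-2 * pi * h / L)
  }
  nl <- tryCatch(
    minpack.lm::nlsLM(f ~ fitfun(z0, C, P, L), data = dat,
                      start = list(z0 = best$z0, C = best$C, P = best$P,
                                   L = best$L),
                      lower = c(best$z0 - 40, 1e-12, 1e-6, 10),
                      upper = c(best$z0 + 40, Inf, Inf, 5000),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  cf <- if (is.null(nl)) best[c("z0", "C", "P", "L")] else as.list(coef(nl))
  if (!all(is.finite(unlist(cf))) || cf$C <= 0 || cf$P <= 0 || cf$L <= 0)
    return(NULL)
  rms <- sqrt(mean((fk - fitfun(cf$z0, cf$C, cf$P, cf$L))^2))
  hz$z0 <- cf$z0
  hz$prefactor <- cf$C
  hz$E <- prefactor_to_E(cf$C, hz$geometry, hz$poisson, hz$front_factor)
  hz$F0 <- cf$P # the saturated brush force under deep indentation
  delta <- pmax(0, (cf$z0 - z) - d)
  sel <- window_select(delta, hertz_window("deep"))
  hz$fit_window <- range(delta[sel])
  hz$n_points <- sum(sel)
  hz$residual_rms <- rms
  hz$data <- list(z = z[sel], force = f[sel], delta = delta[sel])
  br$L <- cf$L
  br$prefactor <- cf$P
  br$N <- prefactor_to_N(cf$P, cf$L, curve$probe$radius, curve$temperature)
  br$residual_rms <- rms
  list(hertz = hz, brush = br)
}

#' Decomposition configuration
#'
#' @param baseline_fraction Far-end fraction for [correct_baseline()].
#' @param hertz_q Deep-window fraction for the Hertz stage.
#' @param poisson Poisson ratio (fixed).
#' @param hertz_offset Co-fit the additive offset absorbing the squeezed
#'   brush plateau; default `TRUE`.
#' @param brush_window Brush validity band as fractions of L.
#' @param joint_refine Refit (z0, E, L, N) jointly against the whole curve
#'   after the staged fits; default `TRUE`. The staged estimates remain the
#'   initialiser and the fallback.
#' @return A configuration list for [decompose_curve()].
#' @export
decompose_config <- function(baseline_fraction = 0.3, hertz_q = 0.4,
                             poisson = 0.5, hertz_offset = TRUE,
                             brush_window = c(0.1, 0.8),
                             joint_refine = TRUE) {
  list(baseline_fraction = baseline_fraction, hertz_q = hertz_q,
       poisson = poisson, hertz_offset = hertz_offset,
       brush_window = brush_window, joint_refine = joint_refine)
}

#' @export
print.curve_decomposition <- function(x, ...) {
  cat("Two-regime force-curve decomposition\n")
  if (is.null(x$hertz)) {
    cat("  no contact detected\n")
  } else {
    cat(sprintf("  E = %.4g Pa (z0 = %.1f nm)\n", x$hertz$E, x$hertz$z0))
    if (x$brush_detected && !is.null(x$brush) && !is.na(x$brush$L))
      cat(sprintf("  glycocalyx L = %.1f nm (N = %.3g m^-2)\n",
                  x$brush$L, x$brush$N))
    else cat("  no brush component fitted\n")
  }
  if (length(x$quality_flags))
    cat("  flags:", paste(x$quality_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.curve_decomposition <- function(object, ...) {
  out <- list(
    E = if (is.null(object$hertz)) NA_real_ else object$hertz$E,
    z0 = if (is.null(object$hertz)) NA_real_ else object$hertz$z0,
    L = if (object$brush_detected) object$brush$L else NA_real_,
    N = if (object$brush_detected) object$brush$N else NA_real_,
    hertz_rms = if (is.null(object$hertz)) NA_real_ else object$hertz$residual_rms,
    brush_r2 = if (object$brush_detected) object$brush$r_squared_loglinear else NA_real_,
    flags = object$quality_flags)
  class(out) <- "summary.curve_decomposition"
  out
}

#' @export
print.summary.curve_decomposition <- function(x, ...) {
  cat(sprintf("E = %.4g Pa | L = %.4g nm | N = %.3g m^-2 | flags: %s\n",
              x$E, x$L, x$N,
              if (length(x$flags)) paste(x$flags, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
coef.curve_decomposition <- function(object, ...) {
  c(E = if (is.null(object$hertz)) NA_real_ else object$hertz$E,
    L = if (object$brush_detected) object$brush$L else NA_real_,
    N = if (object$brush_detected) object$brush$N else NA_real_,
    z0 = if (is.null(object$hertz)) NA_real_ else object$hertz$z0)
}

#' Model force reconstructed from a decomposition
#'
#' Evaluates the fitted two-component model at the curve's own sampled
#' points (using the measured deflection for the kinematic conversion):
#' Hertz contact force past the contact point plus the brush force, which
#' saturates at its prefactor under contact.
#'
#' @param object A `curve_decomposition`.
#' @param ... Unused.
#' @return Predicted force, pN, aligned with the curve samples.
#' @export
predict.curve_decomposition <- function(object, ...) {
  curve <- object$curve
  if (is.null(object$hertz)) return(rep(0, length(curve$z)))
  hz <- object$hertz
  delta <- pmax(0, (hz$z0 - curve$z) - curve$deflection)
  fhat <- hz$prefactor * delta^hz$power
  if (object$brush_detected && !is.na(object$brush$L)) {
    h <- pmax(0, (curve$z - hz$z0) + curve$deflection)
    fhat <- fhat + object$brush$prefactor * exp(-2 * pi * h / object$brush$L)
  } else if (hz$offset) {
    fhat <- fhat + ifelse(delta > 0, hz$F0, 0)
  }
  fhat
}

#' @export
residuals.curve_decomposition <- function(object, ...) {
  object$curve$force - predict(object)
}

#' Simulate curves from a fitted decomposition
#'
#' Parametric bootstrap: draws new synthetic approach curves from the
#' fitted (E, L, N, z0) under the same acquisition settings as the fitted
#' curve, with Gaussian force noise at the fit's residual RMS.
#'
#' @param object A `curve_decomposition` with both components fitted.
#' @param nsim Number of curves.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [force_curve()] objects.
#' @export
simulate.curve_decomposition <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$hertz)) stop("cannot simulate from a no-contact fit")
  if (!is.null(seed)) set.seed(seed)
  cf <- coef(object)
  curve <- object$curve
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(curve = list(
      E = cf[["E"]],
      brush = object$brush_detected,
      L = if (object$brush_detected) cf[["L"]] else 300,
      N = if (object$brush_detected) cf[["N"]] else 1e14,
      z0 = cf[["z0"]],
      noise_sd = object$hertz$residual_rms,
      baseline_offset = 0, baseline_slope = 0,
      n_points = length(curve$z),
      radius = curve$probe$radius,
      k = curve$calibration$spring_constant,
      T = curve$temperature))
    out <- simulate_curve(cfg)$curve
    out$baseline_corrected <- TRUE
    out
  })
}

#' Plot a decomposed force curve
#'
#' Force versus piezo height with the fitted Hertz + brush model overlaid
#' and the contact point marked.
#'
#' @param x A `curve_decomposition`.
#' @param ... Passed to [plot()].
#' @export
plot.curve_decomposition <- function(x, ...) {
  curve <- x$curve
  plot(curve$z, curve$force, pch = 16, cex = 0.4, col = gray(0.6),
       xlab = "piezo height z (nm)", ylab = "force (pN)",
       xlim = rev(range(curve$z)), ...)
  lines(curve$z, predict(x), col = "firebrick", lwd = 2)
  if (!is.null(x$hertz)) abline(v = x$hertz$z0, lty = 3)
  legend("topleft", bty = "n",
         legend = c("data", "Hertz + brush model", "contact point"),
         col = c(gray(0.6), "firebrick", "black"),
         pch = c(16, NA, NA), lty = c(NA, 1, 3))
  invisible(x)
}
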