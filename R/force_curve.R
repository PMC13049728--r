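#' Force-distance curve
#'
#' A single calibrated AFM approach (or retract) segment. Internally the
#' piezo height `z` is in nm and decreases as the tip approaches the surface;
#' the approach segment is stored far-to-near, i.e. with strictly decreasing
#' `z`. Force is in pN and deflection in nm, linked by F = k d through the
#' cantilever spring constant, so supplying either channel determines the
#' other.
#'
#' @param piezo_height Numeric vector of piezo heights, nm; strictly
#'   monotone for the approach segment.
#' @param force Force channel, pN. Supply exactly one of `force`,
#'   `deflection`.
#' @param deflection Cantilever deflection channel, nm.
#' @param segment `"approach"` or `"retract"`.
#' @param position Optional `(x, y)` map position, um.
#' @param temperature Sample temperature, K. Default 309.35 K (36.2 C).
#' @param probe A [probe_geometry()].
#' @param calibration A [cantilever_calibration()].
#' @return An object of class `force_curve`: a list with channels `z`,
#'   `force`, `deflection` and the metadata above.
#' @examples
#' z <- seq(2000, 0, length.out = 64)
#' fc <- force_curve(z, force = pmax(0, 500 - z))
#' fc
#' @export
force_curve <- function(piezo_height, force = NULL, deflection = NULL,
                        segment = c("approach", "retract"),
                        position = NULL, temperature = 309.35,
                        probe = probe_geometry("sphere"),
                        calibration = cantilever_calibration()) {
  segment <- match.arg(segment)
  if (is.null(force) == is.null(deflection))
    stop("supply exactly one of 'force' (pN) or 'deflection' (nm)")
  k <- k_pn_per_nm(calibration)
  if (is.null(force)) force <- k * deflection
  if (is.null(deflection)) deflection <- force / k
  x <- structure(list(z = as.numeric(piezo_height),
                      force = as.numeric(force),
                      deflection = as.numeric(deflection),
                      segment = segment, position = position,
                      temperature = temperature, probe = probe,
                      calibration = calibration,
                      baseline_corrected = FALSE),
                 class = "force_curve")
  validate_force_curve(x)
}

#' Validate a force curve
#'
#' Checks the structural invariants of a [force_curve()]: equal channel
#' lengths of at least 16 samples, a strictly monotone approach ramp,
#' positive temperature and F = k d consistency.
#'
#' @param x A `force_curve`.
#' @return `x`, invisibly-checked; errors describe the violated invariant.
#' @export
validate_force_curve <- function(x) {
  stopifnot(inherits(x, "force_curve"))
  n <- length(x$z)
  if (n < 16L) stop("force curve must have at least 16 samples")
  if (length(x$force) != n || length(x$deflection) != n)
    stop("channel length mismatch: z, force and deflection must agree")
  if (x$segment == "approach") {
    dz <- diff(x$z)
    if (!(all(dz < 0) || all(dz > 0)))
      stop("approach piezo ramp must be strictly monotone")
    if (all(dz > 0)) { # normalise to far-to-near storage
      x$z <- rev(x$z); x$force <- rev(x$force)
      x$deflection <- rev(x$deflection)
    }
  }
  if (!is.finite(x$temperature) || x$temperature <= 0)
    stop("temperature must be positive (K)")
  k <- k_pn_per_nm(x$calibration)
  tol <- 1e-6 * max(1, max(abs(x$force)))
  if (max(abs(x$force - k * x$deflection)) > tol)
    stop("force/deflection inconsistency: force != spring_constant * deflection")
  x
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force-distance curve (%s): %d samples, z in [%.1f, %.1f] nm, max force %.1f pN\n",
              x$segment, length(x$z), min(x$z), max(x$z), max(x$force)))
  cat(sprintf("  probe: %s; k = %.3g N/m; T = %.2f K; baseline %scorrected\n",
              x$probe$kind, x$calibration$spring_constant, x$temperature,
              if (isTRUE(x$baseline_corrected)) "" else "not "))
  if (!is.null(x$position))
    cat(sprintf("  map position: (%.2f, %.2f) um\n",
                x$position[1], x$position[2]))
  invisible(x)
}

# index of the far (non-contact) baseline window: the curve is stored
# far-to-near so these are the leading samples (largest z)
baseline_window_idx <- function(curve, baseline_fraction) {
  n <- length(curve$z)
  m <- floor(baseline_fraction * n)
  if (m < 8L)
    stop("baseline window must contain at least 8 samples; increase baseline_fraction")
  order(curve$z, decreasing = TRUE)[seq_len(m)]
}

#' Baseline-correct a force curve
#'
#' Fits a least-squares straight line to the force channel over the far,
#' non-contact end of the approach (the samples at the largest piezo
#' heights) and subtracts it from the whole curve, removing constant
#' deflection offsets and linear drift/tilt. The deflection channel is
#' rescaled to preserve F = k d. Idempotent to numerical tolerance.
#'
#' @param curve A [force_curve()].
#' @param baseline_fraction Fraction of samples, in (0, 1), taken from the
#'   far end for the line fit; must select at least 8 samples. Default 0.3.
#' @return The corrected `force_curve`, flagged `baseline_corrected`, with
#'   attributes `baseline_coef` (intercept/slope in pN, pN/nm) and
#'   `baseline_rms` (residual RMS over the window, pN).
#' @export
correct_baseline <- function(curve, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  if (!(baseline_fraction > 0 && baseline_fraction < 1))
    stop("baseline_fraction must lie in (0, 1)")
  idx <- baseline_window_idx(curve, baseline_fraction)
  zb <- curve$z[idx]; fb <- curve$force[idx]
  fit <- lm.fit(cbind(1, zb), fb)
  line <- fit$coefficients[1] + fit$coefficients[2] * curve$z
  curve$force <- curve$force - line
  curve$deflection <- curve$force / k_pn_per_nm(curve$calibration)
  curve$baseline_corrected <- TRUE
  attr(curve, "baseline_coef") <- unname(fit$coefficients)
  attr(curve, "baseline_rms") <- sqrt(mean(fit$residuals^2))
  curve
}

#' Convert to tip-sample coordinates
#'
#' Given a contact point `z0`, adds the tip-sample separation
#' s = (z - z0) + d and the indentation delta = max(0, (z0 - z) - d) to the
#' curve, where d is the cantilever deflection (positive under repulsive
#' load, which pushes the tip away from the surface, so s = -delta
#' identically). The piezo height decreases toward the surface, so z > z0
#' is the non-contact side; at z = z0 with d = 0 the indentation is exactly
#' zero.
#'
#' @param curve A baseline-corrected [force_curve()].
#' @param contact_z0 Contact point, nm; must lie within the piezo range.
#' @return The curve with added channels `separation` and `indentation` (nm)
#'   and field `contact_z0`.
#' @export
to_tip_sample <- function(curve, contact_z0) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(contact_z0) || length(contact_z0) != 1L ||
      contact_z0 < min(curve$z) || contact_z0 > max(curve$z))
    stop("contact_z0 outside the curve's piezo range")
  d <- curve$deflection
  curve$separation <- (curve$z - contact_z0) + d
  curve$indentation <- pmax(0, (contact_z0 - curve$z) - d)
  curve$contact_z0 <- contact_z0
  curve
}

require_baseline <- function(curve) {
  if (!isTRUE(curve$baseline_corrected))
    stop("curve must be baseline-corrected first (see correct_baseline)")
  invisible(curve)
}
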